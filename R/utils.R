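#' Derive a sequence of independent seeds from one master seed
#'
#' All stochastic stages draw their seeds from a single stream so that one
#' master seed pins down the whole analysis. Seeds are sampled with the
#' master seed set, so the i-th derived seed depends only on `master` and `i`.
#'
#' @param master Integer master seed.
#' @param n Number of seeds to derive.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seeds <- function(master, n) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Named seed streams for the pipeline stages
#' @keywords internal
seed_streams <- function(master, names) {
  s <- derive_seeds(master, length(names))
  names(s) <- names
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a numeric feature-by-sample matrix as TSV
#'
#' First column `feature_id`, remaining columns one per sample. UTF-8,
#' tab-separated, '.' decimal.
#' @keywords internal
write_feature_tsv <- function(mat, path) {
  df <- data.frame(feature_id = rownames(mat) %||% character(nrow(mat)), mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a feature-by-sample TSV written by [write_feature_tsv()]
#' @keywords internal
read_feature_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          fileEncoding = "UTF-8")
  if (ncol(df) < 1L || names(df)[1L] != "feature_id")
    stop("expected first column 'feature_id' in ", path, call. = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- df$feature_id
  mat
}
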