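#' Construct an omics table
#'
#' The common container for one modality's feature-by-sample matrix plus
#' per-feature annotations. Rows are features, columns samples.
#'
#' @param values Numeric matrix with feature ids as rownames and sample ids
#'   as colnames.
#' @param modality One of `"microbiome"`, `"metabolome"`, `"methylome"`.
#' @param annotations Optional data.frame of per-feature annotations with a
#'   `feature_id` column covering every row of `values`. For the metabolome
#'   the curation step expects columns `identified` (logical) and
#'   `super_pathway`; for the methylome it expects the probe manifest
#'   (`chrom`, `maf`, `promiscuous`, `gene`).
#'
#' @return An object of class `omics_table`: a list with elements `values`,
#'   `modality`, `annotations`.
#' @export
#' @examples
#' m <- matrix(c(0.6, 0.4, 0.3, 0.7), 2, dimnames = list(c("sp1", "sp2"),
#'                                                       c("s1", "s2")))
#' omics_table(m, "microbiome")
omics_table <- function(values, modality = c("microbiome", "metabolome", "methylome"),
                        annotations = NULL) {
  modality <- match.arg(modality)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      (ncol(values) > 0L && is.null(colnames(values))))
    stop("'values' needs feature ids as rownames and sample ids as colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature identifiers", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers", call. = FALSE)
  fin <- values[is.finite(values)]
  if (modality == "methylome" && length(fin) && (min(fin) < 0 || max(fin) > 1))
    stop("methylome beta values must lie in [0, 1]", call. = FALSE)
  if (modality == "microbiome" && length(fin) && min(fin) < 0)
    stop("microbiome abundances must be nonnegative", call. = FALSE)
  if (!is.null(annotations)) {
    if (!is.data.frame(annotations) || is.null(annotations$feature_id))
      stop("'annotations' must be a data.frame with a feature_id column",
           call. = FALSE)
    missing <- setdiff(rownames(values), annotations$feature_id)
    if (length(missing))
      stop("annotations missing for feature(s): ",
           paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
    annotations <- annotations[match(rownames(values), annotations$feature_id), ,
                               drop = FALSE]
    rownames(annotations) <- NULL
  }
  structure(list(values = values, modality = modality,
                 annotations = annotations),
            class = "omics_table")
}

#' @export
print.omics_table <- function(x, ...) {
  cat(sprintf("omics_table [%s]: %d features x %d samples\n",
              x$modality, nrow(x$values), ncol(x$values)))
  if (!is.null(x$annotations))
    cat("  annotations:", paste(setdiff(names(x$annotations), "feature_id"),
                                collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.omics_table <- function(x) dim(x$values)

#' Subset an omics table by feature and/or sample identifiers
#' @param x An `omics_table`.
#' @param features,samples Character vectors of identifiers to keep
#'   (`NULL` keeps all).
#' @return An `omics_table`.
#' @export
subset_omics <- function(x, features = NULL, samples = NULL) {
  stopifnot(inherits(x, "omics_table"))
  v <- x$values
  if (!is.null(features)) {
    missing <- setdiff(features, rownames(v))
    if (length(missing))
      stop("unknown feature(s): ", paste(utils::head(missing, 5L), collapse = ", "),
           call. = FALSE)
    v <- v[features, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(v))
    if (length(missing))
      stop("unknown sample(s): ", paste(utils::head(missing, 5L), collapse = ", "),
           call. = FALSE)
    v <- v[, samples, drop = FALSE]
  }
  ann <- x$annotations
  if (!is.null(ann)) ann <- ann[match(rownames(v), ann$feature_id), , drop = FALSE]
  omics_table(v, x$modality, ann)
}

#' Write / read an omics table as TSV
#'
#' The value matrix goes to `<path>`; annotations, when present, go to a
#' sibling file `<path minus extension>_annotations.tsv`.
#'
#' @param x An `omics_table`.
#' @param path Output TSV path for the value matrix.
#' @return `path`, invisibly.
#' @export
write_omics_table <- function(x, path) {
  stopifnot(inherits(x, "omics_table"))
  write_feature_tsv(x$values, path)
  if (!is.null(x$annotations)) {
    apath <- annotations_path(path)
    utils::write.table(x$annotations, apath, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' @rdname write_omics_table
#' @param modality Modality tag for the table being read.
#' @export
read_omics_table <- function(path, modality) {
  mat <- read_feature_tsv(path)
  apath <- annotations_path(path)
  ann <- NULL
  if (file.exists(apath))
    ann <- utils::read.table(apath, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, quote = "",
                             fileEncoding = "UTF-8")
  omics_table(mat, modality, ann)
}

annotations_path <- function(path) {
  sub("\\.tsv$", "", path) |> paste0("_annotations.tsv")
}
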