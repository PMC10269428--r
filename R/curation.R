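#' Filter report
#'
#' Book-keeping object produced by the curation steps: counts in/out and a
#' per-feature exclusion reason. Reasons used by the package:
#' `allosome`, `snp_maf`, `promiscuous`, `gap_signal`, `unknown_metabolite`,
#' `xenobiotic`, `all_missing`, `low_variance`.
#'
#' @param n_in Features before filtering.
#' @param reasons Named character vector: excluded feature id -> reason.
#' @return A `filter_report` with elements `n_in`, `n_out`, `n_excluded`,
#'   `reasons` and `counts` (exclusions per reason).
#' @export
filter_report <- function(n_in, reasons = character(0)) {
  n_in <- as.integer(n_in)
  n_excluded <- length(reasons)
  rep <- list(n_in = n_in,
              n_out = n_in - n_excluded,
              n_excluded = n_excluded,
              reasons = reasons,
              counts = if (n_excluded) table(factor(reasons)) else table(character(0)))
  if (rep$n_out < 0L) stop("more exclusions than input features", call. = FALSE)
  structure(rep, class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d in, %d excluded, %d out\n",
              x$n_in, x$n_excluded, x$n_out))
  if (x$n_excluded) {
    tab <- x$counts
    for (r in names(tab)) cat(sprintf("  %-18s %d\n", r, tab[[r]]))
  }
  invisible(x)
}

#' Serialise a filter report to JSON
#' @param x A `filter_report`.
#' @param path Output path.
#' @export
write_filter_report <- function(x, path) {
  stopifnot(inherits(x, "filter_report"))
  jsonlite::write_json(list(n_in = x$n_in, n_out = x$n_out,
                            n_excluded = x$n_excluded,
                            counts = as.list(x$counts),
                            reasons = as.list(x$reasons)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Curate a raw metabolite table
#'
#' Reproduces the standard curation of untargeted (Metabolon-style)
#' intensities: (1) drop chemically unidentified metabolites, (2) drop
#' xenobiotics (exogenous compounds), (3) impute each metabolite's
#' below-detection (`NA`) values with its lowest measured raw value — the
#' observed detection floor — and (4) scale each metabolite so its median
#' equals one. Imputation happens on the raw scale, before median scaling,
#' so the imputed value really is the measured floor.
#'
#' @param raw An `omics_table` of modality `"metabolome"` whose annotations
#'   carry `identified` (logical) and `super_pathway` (xenobiotics labelled
#'   `"Xenobiotics"`).
#' @return A list with `table` (curated `omics_table`) and `report`
#'   (a [filter_report()]). Metabolites with no finite value at all are
#'   excluded with reason `all_missing`.
#' @export
#' @examples
#' v <- matrix(c(2, 4, NA), 1, dimnames = list("m1", c("a", "b", "c")))
#' ann <- data.frame(feature_id = "m1", identified = TRUE,
#'                   super_pathway = "Lipid")
#' curate_metabolites(omics_table(v, "metabolome", ann))$table$values
curate_metabolites <- function(raw) {
  stopifnot(inherits(raw, "omics_table"))
  if (raw$modality != "metabolome")
    stop("curate_metabolites expects a metabolome table", call. = FALSE)
  ann <- raw$annotations
  if (is.null(ann) || is.null(ann$identified) || is.null(ann$super_pathway))
    stop("annotations must include 'identified' and 'super_pathway'",
         call. = FALSE)
  v <- raw$values
  reasons <- character(0)

  unknown <- rownames(v)[!ann$identified]
  reasons[unknown] <- "unknown_metabolite"
  keep1 <- setdiff(rownames(v), unknown)

  xeno <- keep1[ann$super_pathway[match(keep1, ann$feature_id)] == "Xenobiotics"]
  reasons[xeno] <- "xenobiotic"
  keep2 <- setdiff(keep1, xeno)

  v <- v[keep2, , drop = FALSE]
  all_na <- rownames(v)[rowSums(is.finite(v)) == 0L]
  reasons[all_na] <- "all_missing"
  v <- v[setdiff(rownames(v), all_na), , drop = FALSE]

  # impute below-detection values with the metabolite's observed minimum,
  # then scale so every metabolite's median is exactly 1
  for (f in seq_len(nrow(v))) {
    row <- v[f, ]
    fin <- is.finite(row)
    row[!fin] <- min(row[fin])
    v[f, ] <- row / stats::median(row)
  }

  ann_out <- ann[match(rownames(v), ann$feature_id), , drop = FALSE]
  list(table = omics_table(v, "metabolome", ann_out),
       report = filter_report(nrow(raw$values), reasons))
}

#' Gap-signal detection for one methylation probe
#'
#' A probe whose beta values split into more than two clusters separated by
#' gaps usually reflects underlying genetic variation rather than epigenetic
#' state. Values are sorted; a new cluster starts wherever the gap between
#' consecutive values exceeds `gap_threshold` on the beta scale; the probe
#' is flagged when more than two clusters result.
#'
#' @param betas Numeric vector of beta values in `[0, 1]` (at least two
#'   finite values).
#' @param gap_threshold Minimum beta gap that separates clusters.
#' @return List with `cluster_count` and `flagged`.
#' @export
#' @examples
#' gaphunt(c(0.10, 0.12, 0.50, 0.52, 0.90), 0.20)  # 3 clusters -> flagged
gaphunt <- function(betas, gap_threshold = 0.20) {
  b <- betas[is.finite(betas)]
  if (length(b) < 2L)
    stop("gaphunt needs at least two finite values", call. = FALSE)
  b <- sort(b)
  k <- 1L + sum(diff(b) > gap_threshold)
  list(cluster_count = k, flagged = k > 2L)
}

#' Exclude unreliable methylation probes
#'
#' Applies the standard EPIC-array probe exclusions in a fixed order, with
#' the first matching rule recorded as the exclusion reason:
#' \enumerate{
#'   \item `allosome` — probe on chrX or chrY (mixed-sex cohorts);
#'   \item `promiscuous` — cross-reactive probe per the manifest flag;
#'   \item `snp_maf` — manifest SNP minor-allele frequency above `maf_cutoff`;
#'   \item `gap_signal` — flagged by [gaphunt()] across the cohort's betas.
#' }
#'
#' @param methylome An `omics_table` of modality `"methylome"` whose
#'   annotations carry the manifest columns `chrom`, `maf`, `promiscuous`.
#' @param maf_cutoff Probes with SNP MAF strictly above this are removed
#'   (default 0.01, i.e. MAF > 1%).
#' @param gap_threshold Passed to [gaphunt()].
#' @return List with `table` (filtered `omics_table`) and `report`.
#' @export
filter_probes <- function(methylome, maf_cutoff = 0.01, gap_threshold = 0.20) {
  stopifnot(inherits(methylome, "omics_table"))
  if (methylome$modality != "methylome")
    stop("filter_probes expects a methylome table", call. = FALSE)
  man <- methylome$annotations
  needed <- c("chrom", "maf", "promiscuous")
  if (is.null(man) || !all(needed %in% names(man)))
    stop("probe manifest with columns chrom, maf, promiscuous is required",
         call. = FALSE)
  probes <- rownames(methylome$values)
  missing <- probes[is.na(match(probes, man$feature_id))]
  if (length(missing))
    stop("probe(s) missing from manifest: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  man <- man[match(probes, man$feature_id), ]

  reasons <- character(0)
  remaining <- probes

  hit <- remaining[man$chrom[match(remaining, man$feature_id)] %in% c("chrX", "chrY")]
  reasons[hit] <- "allosome"; remaining <- setdiff(remaining, hit)

  hit <- remaining[man$promiscuous[match(remaining, man$feature_id)] == 1]
  reasons[hit] <- "promiscuous"; remaining <- setdiff(remaining, hit)

  hit <- remaining[man$maf[match(remaining, man$feature_id)] > maf_cutoff]
  reasons[hit] <- "snp_maf"; remaining <- setdiff(remaining, hit)

  flagged <- vapply(remaining, function(p)
    gaphunt(methylome$values[p, ], gap_threshold)$flagged, logical(1))
  hit <- remaining[flagged]
  reasons[hit] <- "gap_signal"; remaining <- setdiff(remaining, hit)

  list(table = subset_omics(methylome, features = remaining),
       report = filter_report(length(probes), reasons))
}

#' Copies-per-million normalisation
#'
#' Scales every sample (column) of a nonnegative abundance matrix, or a
#' single sample vector, to sum to one million.
#'
#' @param abundances Nonnegative numeric vector or matrix (samples as
#'   columns).
#' @return Same shape as the input, each sample summing to 1e6.
#' @export
#' @examples
#' cpm_normalize(c(1, 3))  # 250000 750000
cpm_normalize <- function(abundances) {
  scale1 <- function(v) {
    if (any(!is.finite(v)) || any(v < 0))
      stop("abundances must be finite and nonnegative", call. = FALSE)
    s <- sum(v)
    if (s == 0) stop("all-zero sample cannot be CPM-normalised", call. = FALSE)
    v * (1e6 / s)
  }
  if (is.matrix(abundances)) apply(abundances, 2L, scale1) else scale1(abundances)
}

#' Paired relative-change (delta) features
#'
#' For each subject with both timepoints, computes per feature
#' `delta = (after - before) / max(|before|, eps_f)` where `eps_f` is the
#' smallest positive value of feature `f` observed anywhere in the cohort
#' (both timepoints). The floor keeps deltas finite and sign-preserving when
#' a feature is absent at baseline. Subjects lacking either timepoint are
#' dropped with a message.
#'
#' @param before,after `omics_table`s with identical feature sets; columns
#'   are the baseline / follow-up samples.
#' @param metadata Data frame with `sample_id`, `subject_id`, `arm`.
#' @return An object of class `delta_matrix`: `values` (subject x feature),
#'   `arm` (named character vector per subject), `modality`, `dropped`
#'   (subjects without a pair).
#' @export
compute_delta <- function(before, after, metadata) {
  stopifnot(inherits(before, "omics_table"), inherits(after, "omics_table"))
  if (!identical(rownames(before$values), rownames(after$values)))
    stop("before/after tables must share an identical feature set",
         call. = FALSE)
  if (!all(c("sample_id", "subject_id", "arm") %in% names(metadata)))
    stop("metadata needs sample_id, subject_id, arm", call. = FALSE)
  sub_of <- stats::setNames(metadata$subject_id, metadata$sample_id)
  arm_of <- stats::setNames(metadata$arm, metadata$subject_id)
  sub_b <- sub_of[colnames(before$values)]
  sub_a <- sub_of[colnames(after$values)]
  if (anyNA(sub_b) || anyNA(sub_a))
    stop("sample(s) missing from metadata", call. = FALSE)
  paired <- intersect(sub_b, sub_a)
  dropped <- setdiff(union(sub_b, sub_a), paired)
  if (!length(paired)) stop("no subjects with both timepoints", call. = FALSE)
  if (length(dropped))
    message("compute_delta: dropping subject(s) without a pair: ",
            paste(dropped, collapse = ", "))

  b <- before$values[, match(paired, sub_b), drop = FALSE]
  a <- after$values[, match(paired, sub_a), drop = FALSE]
  pos_min <- function(v) {
    v <- v[is.finite(v) & v > 0]
    if (length(v)) min(v) else 1
  }
  eps <- vapply(seq_len(nrow(b)), function(f) pos_min(c(b[f, ], a[f, ])),
                numeric(1))
  denom <- pmax(abs(b), eps)   # eps recycles down columns: per-feature floor
  delta <- (a - b) / denom
  delta <- t(delta)
  dimnames(delta) <- list(paired, rownames(before$values))
  structure(list(values = delta,
                 arm = arm_of[paired],
                 modality = before$modality,
                 dropped = dropped),
            class = "delta_matrix")
}

#' @export
print.delta_matrix <- function(x, ...) {
  cat(sprintf("delta_matrix [%s]: %d subjects x %d features (%s)\n",
              x$modality, nrow(x$values), ncol(x$values),
              paste(sprintf("%s n=%d", names(table(x$arm)), table(x$arm)),
                    collapse = ", ")))
  invisible(x)
}

#' Convenience: deltas for one cohort modality
#'
#' Splits a cohort modality table into its two timepoints using the
#' metadata and calls [compute_delta()].
#'
#' @param cohort An `fmt_cohort` or the list returned by [read_cohort()].
#' @param modality `"microbiome"`, `"metabolome"` or `"methylome"`.
#' @param curate Apply the modality's curation step first (metabolite
#'   curation / probe filtering; default `TRUE`).
#' @return A `delta_matrix` (with attribute `"report"` when curated).
#' @export
cohort_deltas <- function(cohort,
                          modality = c("microbiome", "metabolome", "methylome"),
                          curate = TRUE) {
  modality <- match.arg(modality)
  tab <- cohort[[modality]]
  md <- cohort$metadata
  report <- NULL
  if (curate && modality == "metabolome") {
    cur <- curate_metabolites(tab); tab <- cur$table; report <- cur$report
  } else if (curate && modality == "methylome") {
    cur <- filter_probes(tab); tab <- cur$table; report <- cur$report
  }
  tp <- md$timepoint_weeks[match(colnames(tab$values), md$sample_id)]
  before <- subset_omics(tab, samples = colnames(tab$values)[tp == min(tp)])
  after <- subset_omics(tab, samples = colnames(tab$values)[tp == max(tp)])
  dm <- compute_delta(before, after, md)
  attr(dm, "report") <- report
  dm
}
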