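# small in-code fixtures shared across the suite

`%||%` <- function(a, b) if (is.null(a)) b else a

with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

tiny_cohort <- function(seed = 1, ...) {
  generate_cohort(cohort_config(n_species = 40, n_metabolites = 40,
                                n_cpgs = 40, seed = seed, ...))
}

fast_config <- function(seed = 1, ...) {
  ml_config(variance_threshold = 0, select_percentile = 1,
            n_shuffles = 5, n_trees = 50,
            grid = data.frame(max_depth = 2, eta = 0.1), seed = seed, ...)
}

# scaled filtering settings used for synthetic-cohort validation runs:
# microbiome / metabolome use the published thresholds; the methylome
# selection percentile is scaled to the synthetic feature-space size
scaled_ml_config <- function(modality, seed = 1, n_shuffles = 25,
                             n_trees = 200, ...) {
  pct <- c(microbiome = 0.35, metabolome = 0.20, methylome = 0.20)[[modality]]
  vt <- c(microbiome = 0.01, metabolome = 0.25, methylome = 0.027)[[modality]]
  ml_config(variance_threshold = vt, select_percentile = pct,
            n_shuffles = n_shuffles, n_trees = n_trees, seed = seed, ...)
}

# a metabolome table with known annotation structure
toy_metabolome <- function(values, identified = NULL, pathway = NULL) {
  p <- nrow(values)
  ann <- data.frame(feature_id = rownames(values),
                    identified = identified %||% rep(TRUE, p),
                    super_pathway = pathway %||% rep("Lipid", p),
                    stringsAsFactors = FALSE)
  omics_table(values, "metabolome", ann)
}

# a methylome table + manifest with specified per-probe rule violations
toy_methylome <- function(n_probes = 10, n_samples = 8, chrom = NULL,
                          maf = NULL, promiscuous = NULL, betas = NULL,
                          seed = 42) {
  ids <- sprintf("cg%05d", seq_len(n_probes))
  v <- betas %||% with_seed(seed, matrix(stats::runif(n_probes * n_samples, 0.4, 0.6),
                                         n_probes, n_samples))
  dimnames(v) <- list(ids, paste0("s", seq_len(n_samples)))
  man <- data.frame(feature_id = ids,
                    chrom = chrom %||% rep("chr1", n_probes),
                    maf = maf %||% rep(0, n_probes),
                    promiscuous = promiscuous %||% rep(0L, n_probes),
                    gene = paste0("G", seq_len(n_probes)),
                    stringsAsFactors = FALSE)
  omics_table(v, "methylome", man)
}

# paired before/after tables + metadata for delta tests
toy_pair <- function(before, after, arm = NULL) {
  subjects <- paste0("P", seq_len(ncol(before)))
  b <- before; a <- after
  colnames(b) <- paste0(subjects, "_t0")
  colnames(a) <- paste0(subjects, "_t1")
  md <- data.frame(subject_id = rep(subjects, 2),
                   sample_id = c(colnames(b), colnames(a)),
                   arm = rep(arm %||% rep(c("allogenic", "autologous"),
                                          length.out = length(subjects)), 2),
                   timepoint_weeks = rep(c(0L, 24L), each = length(subjects)),
                   stringsAsFactors = FALSE)
  list(before = omics_table(b, "metabolome",
                            data.frame(feature_id = rownames(b),
                                       identified = TRUE,
                                       super_pathway = "Lipid")),
       after = omics_table(a, "metabolome",
                           data.frame(feature_id = rownames(a),
                                      identified = TRUE,
                                      super_pathway = "Lipid")),
       metadata = md)
}
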