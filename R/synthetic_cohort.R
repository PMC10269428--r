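#' Configuration for the synthetic paired two-arm cohort
#'
#' Describes a paired FMT-style study: two arms (allogenic donor FMT versus
#' autologous control), every subject sampled at 0 and 24 weeks across three
#' omics modalities. Defaults mirror a 21-subject trial (10 allogenic,
#' 11 autologous) at a feature scale small enough for routine simulation.
#'
#' @param n_allogenic,n_autologous Subjects per arm.
#' @param n_species,n_metabolites,n_cpgs Features per modality.
#' @param n_planted_per_modality Number of features per modality that receive
#'   an arm-specific shift at week 24 (the "planted" discriminative signal).
#' @param effect_size Standardised magnitude of the planted arm-by-time shift,
#'   on the Cohen's d scale of the per-feature delta distribution.
#' @param missing_rate Fraction of each metabolite's values masked as below
#'   the detection threshold (left-censored to `NA`).
#' @param n_cross_modules Number of planted cross-omics triplets (one species,
#'   one metabolite, one CpG) whose week-24 changes share a per-subject latent
#'   factor, so their deltas correlate across modalities. Modules are drawn
#'   from the planted features, so must not exceed `n_planted_per_modality`.
#' @param seed Master seed; all per-modality random streams derive from it.
#'
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_allogenic = 10, n_autologous = 11,
                          n_species = 120, n_metabolites = 200, n_cpgs = 300,
                          n_planted_per_modality = 5, effect_size = 1.0,
                          missing_rate = 0.1, n_cross_modules = 2, seed = 1) {
  cfg <- list(n_allogenic = as.integer(n_allogenic),
              n_autologous = as.integer(n_autologous),
              n_species = as.integer(n_species),
              n_metabolites = as.integer(n_metabolites),
              n_cpgs = as.integer(n_cpgs),
              n_planted_per_modality = as.integer(n_planted_per_modality),
              effect_size = as.numeric(effect_size),
              missing_rate = as.numeric(missing_rate),
              n_cross_modules = as.integer(n_cross_modules),
              seed = as.integer(seed))
  counts <- cfg[c("n_allogenic", "n_autologous", "n_species", "n_metabolites",
                  "n_cpgs", "n_planted_per_modality", "n_cross_modules")]
  if (any(vapply(counts, function(v) is.na(v) || v < 0L, logical(1))))
    stop("all counts must be >= 0", call. = FALSE)
  if (is.na(cfg$missing_rate) || cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  if (is.na(cfg$effect_size) || cfg$effect_size < 0)
    stop("effect_size must be >= 0", call. = FALSE)
  if (cfg$n_planted_per_modality >
      min(cfg$n_species, cfg$n_metabolites, cfg$n_cpgs))
    stop("n_planted_per_modality exceeds a modality's feature count",
         call. = FALSE)
  if (cfg$n_cross_modules > cfg$n_planted_per_modality)
    stop("n_cross_modules must not exceed n_planted_per_modality",
         call. = FALSE)
  structure(cfg, class = "cohort_config")
}

with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Latent Gaussian machinery shared by the three modalities.
# value(f, subject, time) = mu_f + baseline_(f,s) + noise_(f,s,t)
#                           + planted arm-by-time shift + module factor,
# then pushed through a modality-specific link (exp / exp / plogis).
# The planted shift acts at week 24 only, in the allogenic arm, scaled so the
# between-arm difference in delta units equals `effect_size` Cohen's d.
gen_latent <- function(p, arm, mu, sd_subject, sd_time, effect_size,
                       planted_idx, module_of, z, module_loading) {
  nsub <- length(arm)
  base <- matrix(stats::rnorm(p * nsub, sd = sd_subject), p, nsub) + mu
  e0 <- matrix(stats::rnorm(p * nsub, sd = sd_time), p, nsub)
  e1 <- matrix(stats::rnorm(p * nsub, sd = sd_time), p, nsub)
  w0 <- base + e0
  w1 <- base + e1
  sd_delta <- sqrt(2) * sd_time
  if (length(planted_idx)) {
    allo <- arm == "allogenic"
    w1[planted_idx, allo] <- w1[planted_idx, allo] + effect_size * sd_delta
  }
  if (length(module_of)) {
    # members share the factor z but keep the same total delta variance as
    # any other feature: own time noise shrinks by c = sqrt(1 + lambda^2)
    # while the factor enters with loading lambda/c, so the pairwise latent
    # correlation is lambda^2 / (1 + lambda^2) and the latent delta sd stays
    # sd_delta
    c2 <- sqrt(1 + module_loading^2)
    for (k in seq_along(module_of)) {
      f <- as.integer(names(module_of)[k])
      w0[f, ] <- base[f, ] + e0[f, ] / c2
      w1[f, ] <- base[f, ] + e1[f, ] / c2 +
        (module_loading / c2) * sd_delta * z[, module_of[k]]
    }
  }
  list(w0 = w0, w1 = w1)
}

#' Generate a synthetic paired multi-omics cohort
#'
#' Draws a full two-arm, two-timepoint cohort with the statistical structure
#' the analysis assumes: compositional microbiome relative abundances
#' (exponentiated correlated Gaussians closed to sum 1), log-normal metabolite
#' intensities with left-censored below-detection missingness, logit-normal
#' methylation beta values, ordinal histology scores, planted arm-by-time
#' effects and cross-omics correlated modules tied through a shared
#' per-subject latent factor. The same seed reproduces the cohort exactly.
#'
#' @param config A [cohort_config()].
#' @return An object of class `fmt_cohort`: omics tables `microbiome`,
#'   `metabolome`, `methylome` (columns cover both timepoints), `metadata`
#'   (subject_id, sample_id, arm, timepoint_weeks), `histology` per-subject
#'   ordinal scores, and `truth` (planted feature ids, cross-module triplets,
#'   the histology-associated CpG).
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_species = 30, n_metabolites = 30,
#'                                      n_cpgs = 30, seed = 7))
#' coh
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  nsub <- cfg$n_allogenic + cfg$n_autologous
  subjects <- sprintf("S%02d", seq_len(nsub))
  arm <- rep(c("allogenic", "autologous"), c(cfg$n_allogenic, cfg$n_autologous))
  samples0 <- paste0(subjects, "_wk0")
  samples1 <- paste0(subjects, "_wk24")
  metadata <- data.frame(
    subject_id = rep(subjects, 2L),
    sample_id = c(samples0, samples1),
    arm = rep(arm, 2L),
    timepoint_weeks = rep(c(0L, 24L), each = nsub),
    stringsAsFactors = FALSE)

  streams <- seed_streams(cfg$seed, c("plant", "modules", "microbiome",
                                      "metabolome", "methylome", "annotations",
                                      "histology"))

  # Members of a module share lambda * sd_delta * z_s at week 24, on top of
  # independent delta noise with variance sd_delta^2, giving latent pairwise
  # correlation lambda^2 / (lambda^2 + 1). The link nonlinearities and the
  # relative-change transform attenuate this; lambda = 2.8 realises a delta
  # Spearman |rho| near 0.8 at n = 21. Module members take their arm shift
  # through the factor itself (allogenic subjects' z is shifted by
  # effect_size * sqrt(1 + lambda^2) / lambda), so each member's
  # between-arm delta separation is effect_size Cohen's d, the same as for
  # directly planted features.
  module_loading <- 2.5
  z <- with_seed(streams["modules"], {
    zm <- matrix(stats::rnorm(nsub * max(cfg$n_cross_modules, 1L)), nsub)
    z_shift <- cfg$effect_size * sqrt(1 + module_loading^2) / module_loading
    zm[arm == "allogenic", ] <- zm[arm == "allogenic", ] + z_shift
    zm
  })

  plant <- with_seed(streams["plant"], {
    lapply(c(microbiome = cfg$n_species, metabolome = cfg$n_metabolites,
             methylome = cfg$n_cpgs),
           function(p) if (p > 0L) sort(sample.int(p, cfg$n_planted_per_modality))
           else integer(0))
  })
  # cross-module members are the first planted features of each modality
  module_of <- lapply(plant, function(idx) {
    if (cfg$n_cross_modules == 0L) return(integer(0))
    m <- seq_len(cfg$n_cross_modules)
    stats::setNames(m, as.character(idx[m]))
  })
  module_map <- lapply(module_of, function(m) stats::setNames(as.integer(names(m)), m))
  # module members are shifted via the factor, not directly
  direct <- lapply(names(plant), function(m)
    setdiff(plant[[m]], as.integer(names(module_of[[m]]))))
  names(direct) <- names(plant)

  feat_ids <- list(
    microbiome = if (cfg$n_species) sprintf("sp_%03d", seq_len(cfg$n_species)) else character(0),
    metabolome = if (cfg$n_metabolites) sprintf("met_%03d", seq_len(cfg$n_metabolites)) else character(0),
    methylome = if (cfg$n_cpgs) sprintf("cg%08d", seq_len(cfg$n_cpgs)) else character(0))

  ## --- microbiome: compositional relative abundances -----------------------
  micro <- with_seed(streams["microbiome"], {
    p <- cfg$n_species
    mu <- stats::rnorm(p, 0, 2)
    lat <- gen_latent(p, arm, mu, sd_subject = 0.7, sd_time = 0.3,
                      cfg$effect_size, direct$microbiome,
                      module_of$microbiome, z, module_loading)
    a0 <- exp(lat$w0); a1 <- exp(lat$w1)
    close_unit <- function(m) {
      if (nrow(m) == 0L) return(m)
      sweep(m, 2L, colSums(m), "/")
    }
    cbind(close_unit(a0), close_unit(a1))
  })
  dimnames(micro) <- list(feat_ids$microbiome, c(samples0, samples1))

  ## --- metabolome: log-normal intensities, left-censored -------------------
  metab <- with_seed(streams["metabolome"], {
    p <- cfg$n_metabolites
    mu <- stats::rnorm(p, 10, 1.5)
    lat <- gen_latent(p, arm, mu, sd_subject = 0.6, sd_time = 0.35,
                      cfg$effect_size, direct$metabolome,
                      module_of$metabolome, z, module_loading)
    x <- exp(cbind(lat$w0, lat$w1))
    if (cfg$missing_rate > 0 && p > 0L) {
      # per-metabolite detection floor: the missing_rate quantile of its
      # own intensities; values strictly below are "below detection"
      for (f in seq_len(p)) {
        floor_f <- stats::quantile(x[f, ], probs = cfg$missing_rate,
                                   names = FALSE, type = 7)
        x[f, x[f, ] < floor_f] <- NA_real_
      }
    }
    x
  })
  dimnames(metab) <- list(feat_ids$metabolome, c(samples0, samples1))

  ## --- methylome: logit-normal beta values ---------------------------------
  hist_latent <- with_seed(streams["histology"], stats::rnorm(nsub))
  methylome_res <- with_seed(streams["methylome"], {
    p <- cfg$n_cpgs
    mu <- stats::rnorm(p, 0, 1.8)
    # planted CpGs sit mid-range so their relative beta changes are visible
    mu[plant$methylome] <- stats::rnorm(length(plant$methylome), 0, 0.5)
    lat <- gen_latent(p, arm, mu, sd_subject = 0.5, sd_time = 0.4,
                      cfg$effect_size, direct$methylome,
                      module_of$methylome, z, module_loading)
    # one non-planted probe tracks the histology latent at both timepoints,
    # exercising the baseline methylation / histology correlation stage
    hist_cpg <- integer(0)
    free <- setdiff(seq_len(p), plant$methylome)
    if (length(free)) {
      hist_cpg <- free[1L]
      lat$w0[hist_cpg, ] <- lat$w0[hist_cpg, ] + 0.9 * hist_latent
      lat$w1[hist_cpg, ] <- lat$w1[hist_cpg, ] + 0.9 * hist_latent
    }
    w <- cbind(lat$w0, lat$w1)
    beta <- array(stats::plogis(w), dim = dim(w))
    list(beta = beta, hist_cpg = hist_cpg)
  })
  beta <- methylome_res$beta
  dimnames(beta) <- list(feat_ids$methylome, c(samples0, samples1))

  ## --- annotations ---------------------------------------------------------
  ann <- with_seed(streams["annotations"], {
    met_ann <- NULL
    if (cfg$n_metabolites > 0L) {
      pathways <- c("Lipid", "Amino Acid", "Carbohydrate", "Nucleotide",
                    "Peptide", "Cofactors and Vitamins", "Xenobiotics")
      sp <- sample(pathways, cfg$n_metabolites, replace = TRUE,
                   prob = c(0.30, 0.20, 0.10, 0.08, 0.08, 0.09, 0.15))
      identified <- stats::runif(cfg$n_metabolites) > 0.15
      # planted metabolites must survive curation
      identified[plant$metabolome] <- TRUE
      sp[plant$metabolome] <- "Lipid"
      met_ann <- data.frame(feature_id = feat_ids$metabolome,
                            identified = identified, super_pathway = sp,
                            stringsAsFactors = FALSE)
    }
    manifest <- NULL
    if (cfg$n_cpgs > 0L) {
      chrom <- sample(c(paste0("chr", 1:22), "chrX", "chrY"), cfg$n_cpgs,
                      replace = TRUE, prob = c(rep(0.94 / 22, 22), 0.04, 0.02))
      maf <- ifelse(stats::runif(cfg$n_cpgs) < 0.08,
                    stats::runif(cfg$n_cpgs, 0, 0.3), 0)
      promiscuous <- as.integer(stats::runif(cfg$n_cpgs) < 0.03)
      keep <- c(plant$methylome, methylome_res$hist_cpg)
      chrom[keep] <- "chr1"; maf[keep] <- 0; promiscuous[keep] <- 0L
      manifest <- data.frame(feature_id = feat_ids$methylome,
                             probe_id = feat_ids$methylome,
                             chrom = chrom, maf = maf,
                             promiscuous = promiscuous,
                             gene = sprintf("GENE%04d", seq_len(cfg$n_cpgs)),
                             stringsAsFactors = FALSE)
    }
    list(metabolome = met_ann, manifest = manifest)
  })

  ## --- histology: ordinal scores, ballooning tied to the same latent -------
  histology <- with_seed(streams["histology"] + 1L, {
    noise <- function(s = 1) stats::rnorm(nsub, sd = s)
    clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
    data.frame(
      subject_id = subjects,
      steatosis_pct = round(clamp(35 + 20 * noise(), 5, 90)),
      nas = as.integer(clamp(round(3 + 1.2 * noise()), 0, 8)),
      necro_inflammation = as.integer(clamp(round(1 + 0.8 * noise()), 0, 2)),
      fibrosis = as.integer(clamp(round(1 + 0.9 * noise()), 0, 4)),
      ballooning = as.integer(clamp(round(1 + 0.8 * hist_latent), 0, 2)),
      stringsAsFactors = FALSE)
  })

  truth <- list(
    planted = lapply(stats::setNames(nm = names(feat_ids)), function(m)
      feat_ids[[m]][plant[[m]]]),
    modules = if (cfg$n_cross_modules > 0L)
      data.frame(module = seq_len(cfg$n_cross_modules),
                 microbiome = feat_ids$microbiome[module_map$microbiome],
                 metabolome = feat_ids$metabolome[module_map$metabolome],
                 methylome = feat_ids$methylome[module_map$methylome],
                 stringsAsFactors = FALSE)
    else data.frame(module = integer(0), microbiome = character(0),
                    metabolome = character(0), methylome = character(0)),
    histology_cpg = if (length(methylome_res$hist_cpg))
      feat_ids$methylome[methylome_res$hist_cpg] else character(0),
    histology_score = "ballooning")

  structure(list(
    microbiome = omics_table(micro, "microbiome"),
    metabolome = omics_table(metab, "metabolome", ann$metabolome),
    methylome = omics_table(beta, "methylome", ann$manifest),
    metadata = metadata,
    histology = histology,
    truth = truth,
    config = cfg), class = "fmt_cohort")
}

#' @export
print.fmt_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Synthetic paired FMT cohort: %d allogenic + %d autologous subjects, %d samples\n",
              cfg$n_allogenic, cfg$n_autologous, nrow(x$metadata)))
  cat(sprintf("  microbiome %d species | metabolome %d metabolites | methylome %d CpGs\n",
              nrow(x$microbiome$values), nrow(x$metabolome$values),
              nrow(x$methylome$values)))
  cat(sprintf("  planted: %d features/modality (effect size %.2f), %d cross-omics module(s)\n",
              cfg$n_planted_per_modality, cfg$effect_size, cfg$n_cross_modules))
  invisible(x)
}

#' Write a cohort to a directory of TSV files
#'
#' One value matrix per modality (`microbiome.tsv`, `metabolome.tsv`,
#' `methylome.tsv`, samples of both timepoints as columns), plus
#' `metabolome_annotations.tsv`, `methylome_annotations.tsv` (the probe
#' manifest), `metadata.tsv` and `histology.tsv`. The files round-trip
#' losslessly through [read_cohort()].
#'
#' @param cohort An `fmt_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fmt_cohort"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory: ", dir, call. = FALSE)
  for (m in c("microbiome", "metabolome", "methylome"))
    write_omics_table(cohort[[m]], file.path(dir, paste0(m, ".tsv")))
  utils::write.table(cohort$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$histology, file.path(dir, "histology.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @return `read_cohort()` returns a list with the three omics tables,
#'   `metadata` and `histology` (the generator's `truth` is not persisted).
#' @export
read_cohort <- function(dir) {
  if (!dir.exists(dir)) stop("directory not found: ", dir, call. = FALSE)
  out <- list()
  for (m in c("microbiome", "metabolome", "methylome"))
    out[[m]] <- read_omics_table(file.path(dir, paste0(m, ".tsv")), m)
  out$metadata <- utils::read.table(file.path(dir, "metadata.tsv"), sep = "\t",
                                    header = TRUE, stringsAsFactors = FALSE)
  out$histology <- utils::read.table(file.path(dir, "histology.tsv"), sep = "\t",
                                     header = TRUE, stringsAsFactors = FALSE)
  out
}
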