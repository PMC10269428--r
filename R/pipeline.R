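#' End-to-end pipeline configuration
#'
#' Aggregates all stage parameters in one place. Exactly one of
#' `input_dir` (a directory written by [write_cohort()] or following the
#' same TSV layout) or `cohort` (a [cohort_config()] to simulate) must be
#' given.
#'
#' @param cohort A [cohort_config()], or `NULL` when reading from disk.
#' @param input_dir Directory of input TSVs, or `NULL` when simulating.
#' @param ml Named list of [ml_config()]s per modality; defaults to
#'   [default_ml_config()] of each modality.
#' @param network A [network_config()].
#' @param n_perm Permutations for the AUC significance test; `0` skips it.
#' @param out_dir Output directory, or `NULL` for no file output.
#' @param seed Master seed for every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(), input_dir = NULL,
                            ml = NULL, network = network_config(),
                            n_perm = 0, out_dir = NULL, seed = 1) {
  if (is.null(cohort) == is.null(input_dir))
    stop("give exactly one of 'cohort' or 'input_dir'", call. = FALSE)
  modalities <- c("microbiome", "metabolome", "methylome")
  if (is.null(ml))
    ml <- stats::setNames(lapply(modalities, default_ml_config), modalities)
  stopifnot(all(modalities %in% names(ml)))
  structure(list(cohort = cohort, input_dir = input_dir, ml = ml,
                 network = network, n_perm = as.integer(n_perm),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf("[fmtomics] %s", sprintf(fmt, ...)))
}

#' Run the full multi-omics analysis pipeline
#'
#' Executes simulate/load -> curate -> deltas -> per-modality
#' stability-selection classification (optionally with a permutation test)
#' -> importance ranking -> cross-omics network -> histology correlations,
#' and assembles a machine-readable report. When `config$out_dir` is set,
#' the report (JSON), ranked features, per-shuffle AUCs, the network edge
#' list and GraphML are written there.
#'
#' @param config A [pipeline_config()].
#' @param verbose Log stage progress to stderr.
#' @return Class `fmt_report`: a list with `seed`, `filter_reports`,
#'   `stability` (per modality: auc vector, mean/sd, features, top ranked),
#'   `permutation` (if run), `network` summary, `histology` top
#'   correlations, and `timing` (elapsed seconds per stage).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  modalities <- c("microbiome", "metabolome", "methylome")
  timing <- list(); t_stage <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- force(expr)
    list(value = v, secs = proc.time()[["elapsed"]] - t0)
  }

  st <- t_stage({
    if (!is.null(config$input_dir)) {
      stage_log(verbose, "loading cohort from %s", config$input_dir)
      read_cohort(config$input_dir)
    } else {
      cfg <- config$cohort; cfg$seed <- config$seed
      stage_log(verbose, "simulating cohort (seed %d)", cfg$seed)
      generate_cohort(cfg)
    }
  })
  cohort <- st$value; timing$cohort <- st$secs

  st <- t_stage({
    deltas <- list(); reports <- list()
    for (m in modalities) {
      dm <- cohort_deltas(cohort, m, curate = TRUE)
      reports[[m]] <- attr(dm, "report")
      attr(dm, "report") <- NULL
      deltas[[m]] <- dm
      stage_log(verbose, "%s: %d subjects x %d delta features", m,
                nrow(dm$values), ncol(dm$values))
    }
    list(deltas = deltas, reports = reports)
  })
  deltas <- st$value$deltas; reports <- st$value$reports
  timing$curation <- st$secs

  ml_seeds <- seed_streams(config$seed, paste0("ml_", modalities))
  fits <- list(); ranked <- list(); perms <- list()
  for (m in modalities) {
    st <- t_stage({
      cfg <- config$ml[[m]]
      cfg$seed <- ml_seeds[[paste0("ml_", m)]]
      fit <- stability_run(deltas[[m]], cfg)
      perm <- NULL
      if (config$n_perm > 0L)
        perm <- permutation_test(deltas[[m]], cfg, n_perm = config$n_perm,
                                 observed = fit)
      list(fit = fit, perm = perm)
    })
    fits[[m]] <- st$value$fit
    perms[[m]] <- st$value$perm
    ranked[[m]] <- rank_importance(fits[[m]],
                                   min(config$network$top_k,
                                       length(fits[[m]]$features)))
    timing[[paste0("classify_", m)]] <- st$secs
    stage_log(verbose, "%s: mean AUC %.3f (SD %.3f)%s", m,
              fits[[m]]$mean_auc, fits[[m]]$sd_auc,
              if (!is.null(perms[[m]]))
                sprintf(", permutation p = %.4g", perms[[m]]$p_value) else "")
  }

  st <- t_stage(build_network(deltas, ranked, config$network))
  net <- st$value; timing$network <- st$secs
  stage_log(verbose, "network: %d nodes, %d edges", nrow(net$nodes),
            nrow(net$edges))

  st <- t_stage({
    hb <- methylome_baseline(cohort)
    correlate_histology(hb, cohort$histology)
  })
  histo <- st$value; timing$histology <- st$secs

  report <- structure(list(
    seed = config$seed,
    filter_reports = lapply(reports, function(r) if (is.null(r)) NULL else
      list(n_in = r$n_in, n_out = r$n_out, counts = as.list(r$counts))),
    stability = stats::setNames(lapply(modalities, function(m) list(
      auc = fits[[m]]$auc,
      mean_auc = fits[[m]]$mean_auc,
      sd_auc = fits[[m]]$sd_auc,
      n_features = length(fits[[m]]$features),
      top_features = ranked[[m]])), modalities),
    permutation = if (config$n_perm > 0L)
      stats::setNames(lapply(modalities, function(m) list(
        p_value = perms[[m]]$p_value,
        observed_auc = perms[[m]]$observed_auc,
        null_mean_auc = mean(perms[[m]]$null_auc))), modalities) else NULL,
    network = list(n_nodes = nrow(net$nodes), n_edges = nrow(net$edges),
                   rho_cutoff = net$config$rho_cutoff,
                   edges = net$edges),
    histology_correlations = utils::head(histo, 20L),
    timing = timing), class = "fmt_report")
  attr(report, "fits") <- fits
  attr(report, "network") <- net

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(report, file.path(config$out_dir, "report.json"))
    for (m in modalities) {
      utils::write.table(ranked[[m]],
                         file.path(config$out_dir, paste0("ranked_", m, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(data.frame(shuffle = seq_along(fits[[m]]$auc),
                                    auc = fits[[m]]$auc),
                         file.path(config$out_dir, paste0("auc_", m, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    export_network(net, file.path(config$out_dir, "network_edges.tsv"),
                   file.path(config$out_dir, "network.graphml"))
    stage_log(verbose, "outputs written to %s", config$out_dir)
  }
  report
}

# baseline (week 0) methylome slice as subjects x CpGs
methylome_baseline <- function(cohort) {
  md <- cohort$metadata
  tab <- cohort$methylome
  base_samples <- md$sample_id[md$timepoint_weeks == min(md$timepoint_weeks)]
  base_samples <- intersect(colnames(tab$values), base_samples)
  m <- t(tab$values[, base_samples, drop = FALSE])
  rownames(m) <- md$subject_id[match(base_samples, md$sample_id)]
  m
}

#' @export
print.fmt_report <- function(x, ...) {
  cat("fmtomics pipeline report (seed", x$seed, ")\n")
  for (m in names(x$stability))
    cat(sprintf("  %-11s mean AUC %.3f (SD %.3f), %d features\n", m,
                x$stability[[m]]$mean_auc, x$stability[[m]]$sd_auc,
                x$stability[[m]]$n_features))
  cat(sprintf("  network: %d nodes, %d edges at |rho| >= %.2f\n",
              x$network$n_nodes, x$network$n_edges, x$network$rho_cutoff))
  invisible(x)
}

#' Write / validate the pipeline report
#'
#' `write_report()` serialises an `fmt_report` as JSON.
#' `validate_report()` checks a report (or a JSON file) against the report
#' schema shipped in `inst/extdata/report-schema.json`: all required keys
#' must be present with the expected JSON types.
#'
#' @param report An `fmt_report` or (for validation) a path to a report
#'   JSON file.
#' @param path Output path.
#' @return `validate_report()` returns `TRUE` invisibly or stops with the
#'   missing/mistyped field.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "fmt_report"))
  out <- unclass(report)
  attributes(out) <- list(names = names(out))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
validate_report <- function(report) {
  if (is.character(report)) report <- jsonlite::read_json(report)
  schema <- jsonlite::read_json(system.file("extdata", "report-schema.json",
                                            package = "fmtomics"))
  check <- function(obj, sch, where) {
    type <- sch$type
    ok <- switch(type,
      object = is.list(obj),
      array = is.list(obj) || is.vector(obj),
      number = is.numeric(obj) || (is.list(obj) && all(vapply(obj, is.numeric, logical(1)))),
      integer = is.numeric(obj),
      string = is.character(obj),
      TRUE)
    if (!ok) stop("report field '", where, "' is not of type ", type,
                  call. = FALSE)
    if (type == "object" && !is.null(sch$required))
      for (key in unlist(sch$required)) {
        if (is.null(obj[[key]]))
          stop("report is missing required field '",
               paste0(where, ".", key), "'", call. = FALSE)
        if (!is.null(sch$properties[[key]]))
          check(obj[[key]], sch$properties[[key]], paste0(where, ".", key))
      }
    invisible(TRUE)
  }
  check(report, schema, "report")
  invisible(TRUE)
}

#' Baseline-characteristics table
#'
#' Builds a Table-1-style summary: per variable, the arm-wise summary in the
#' convention matching its type and the p-value of the matching test —
#' mean ± SD with a two-sample t-test for `continuous_normal`,
#' median [IQR] with a Mann-Whitney U test for `continuous_skewed`, counts
#' with the exact Fisher-Freeman-Halton test for `categorical`. p-values
#' are computed at full precision and rounded to two decimals only in the
#' output column.
#'
#' @param data Data frame with one row per subject, an `arm` column and the
#'   variables to summarise.
#' @param variables Data frame with columns `variable` and `type`
#'   (`continuous_normal`, `continuous_skewed`, `categorical`).
#' @param ttest_variant Passed to [ttest_from_summary()].
#' @return Data frame with `variable`, one summary column per arm, `p`
#'   (2-decimal character) and `p_exact` (numeric).
#' @export
make_table1 <- function(data, variables, ttest_variant = "welch") {
  stopifnot(all(c("variable", "type") %in% names(variables)),
            "arm" %in% names(data))
  arms <- sort(unique(data$arm))
  if (length(arms) != 2L) stop("exactly two arms expected", call. = FALSE)
  rows <- lapply(seq_len(nrow(variables)), function(i) {
    v <- variables$variable[i]; type <- variables$type[i]
    if (!v %in% names(data)) stop("variable not in data: ", v, call. = FALSE)
    g1 <- data[[v]][data$arm == arms[1]]
    g2 <- data[[v]][data$arm == arms[2]]
    if (type == "continuous_normal") {
      s <- function(g) sprintf("%.1f ± %.1f", mean(g), stats::sd(g))
      p <- ttest_from_summary(c(n = length(g1), mean = mean(g1), sd = stats::sd(g1)),
                              c(n = length(g2), mean = mean(g2), sd = stats::sd(g2)),
                              variant = ttest_variant)$p.value
      c(s(g1), s(g2), p)
    } else if (type == "continuous_skewed") {
      s <- function(g) sprintf("%.1f [%.1f-%.1f]", stats::median(g),
                               stats::quantile(g, 0.25), stats::quantile(g, 0.75))
      c(s(g1), s(g2), mann_whitney(g1, g2)$p.value)
    } else if (type == "categorical") {
      tab <- table(factor(data[[v]]), factor(data$arm, levels = arms))
      s <- function(col) paste(tab[, col], collapse = "/")
      c(s(1), s(2), fisher_exact_rxc(tab)$p.value)
    } else stop("unknown variable type: ", type, call. = FALSE)
  })
  p_exact <- as.numeric(vapply(rows, `[`, character(1), 3L))
  out <- data.frame(variable = variables$variable,
                    a = vapply(rows, `[`, character(1), 1L),
                    b = vapply(rows, `[`, character(1), 2L),
                    p = sprintf("%.2f", p_exact),
                    p_exact = p_exact,
                    stringsAsFactors = FALSE)
  names(out)[2:3] <- arms
  out
}
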