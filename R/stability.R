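#' Stability-selection classifier configuration
#'
#' Parameters of the repeated train/test classification procedure. The
#' shipped per-modality defaults ([default_ml_config()]) are the full-scale
#' settings of the analysis design: 100 reshuffles, 80/20 stratified splits,
#' 3-fold cross-validated hyperparameter tuning, and a gradient-boosted tree
#' ensemble with 2000 trees. Smaller values of `n_shuffles` / `n_trees` are
#' configuration for quick runs, not a different procedure.
#'
#' @param variance_threshold Features with sample variance at or below this
#'   are dropped before modelling (per-modality defaults: microbiome 0.01,
#'   metabolome 0.25, methylome 0.027).
#' @param select_percentile Fraction of (variance-surviving) features kept
#'   by the univariate ANOVA-F selection (defaults: 35%, 20%, 1%).
#' @param n_shuffles Number of random train/test partitions.
#' @param test_fraction Held-out fraction per partition.
#' @param cv_folds Folds for hyperparameter tuning inside the training set.
#' @param n_trees Boosting rounds of the final (and tuning) models.
#' @param grid Data frame of candidate hyperparameters, columns `max_depth`
#'   and `eta`. A single-row grid skips cross-validation.
#' @param seed Seed for the partition/tuning streams.
#' @return An `ml_config` list.
#' @export
ml_config <- function(variance_threshold = 0.01, select_percentile = 0.35,
                      n_shuffles = 100, test_fraction = 0.2, cv_folds = 3,
                      n_trees = 2000,
                      grid = expand.grid(max_depth = c(2, 3),
                                         eta = c(0.05, 0.1)),
                      seed = 1) {
  cfg <- list(variance_threshold = as.numeric(variance_threshold),
              select_percentile = as.numeric(select_percentile),
              n_shuffles = as.integer(n_shuffles),
              test_fraction = as.numeric(test_fraction),
              cv_folds = as.integer(cv_folds),
              n_trees = as.integer(n_trees),
              grid = as.data.frame(grid),
              seed = as.integer(seed))
  if (cfg$test_fraction <= 0 || cfg$test_fraction >= 1)
    stop("test_fraction must lie in (0, 1)", call. = FALSE)
  if (cfg$cv_folds < 2L) stop("cv_folds must be >= 2", call. = FALSE)
  if (cfg$n_trees < 1L) stop("n_trees must be >= 1", call. = FALSE)
  if (cfg$n_shuffles < 1L) stop("n_shuffles must be >= 1", call. = FALSE)
  if (!all(c("max_depth", "eta") %in% names(cfg$grid)) || !nrow(cfg$grid))
    stop("grid needs columns max_depth and eta and at least one row",
         call. = FALSE)
  structure(cfg, class = "ml_config")
}

#' @rdname ml_config
#' @param modality Modality whose published filtering settings to use.
#' @param ... Overrides passed on to [ml_config()].
#' @export
default_ml_config <- function(modality = c("microbiome", "metabolome",
                                           "methylome"), ...) {
  modality <- match.arg(modality)
  defaults <- switch(modality,
    microbiome = list(variance_threshold = 0.01, select_percentile = 0.35),
    metabolome = list(variance_threshold = 0.25, select_percentile = 0.20),
    methylome = list(variance_threshold = 0.027, select_percentile = 0.01))
  do.call(ml_config, utils::modifyList(defaults, list(...)))
}

#' Unsupervised variance filter
#'
#' Removes features whose sample variance across subjects is not strictly
#' above `threshold`, independent of the arm labels.
#'
#' @param deltas A `delta_matrix`.
#' @param threshold Variance threshold (strict `>` retains).
#' @return A `delta_matrix` restricted to the surviving features (order
#'   preserved).
#' @export
variance_filter <- function(deltas, threshold) {
  stopifnot(inherits(deltas, "delta_matrix"), threshold >= 0)
  v <- apply(deltas$values, 2L, stats::var)
  keep <- which(v > threshold)
  if (!length(keep))
    stop("variance filter at threshold ", threshold, " removed every feature",
         call. = FALSE)
  out <- deltas
  out$values <- deltas$values[, keep, drop = FALSE]
  out
}

#' Univariate ANOVA-F feature selection
#'
#' Scores every feature by the one-way ANOVA F statistic between the two
#' arms and keeps the top `ceiling(percentile * n_features)`. Ties are
#' broken by feature identifier so selection is deterministic.
#'
#' @param deltas A `delta_matrix` carrying the arm labels.
#' @param percentile Fraction of features to keep, in (0, 1].
#' @return A `delta_matrix` with the selected features, original column
#'   order preserved.
#' @export
univariate_select <- function(deltas, percentile) {
  stopifnot(inherits(deltas, "delta_matrix"),
            percentile > 0, percentile <= 1)
  labels <- deltas$arm
  if (length(unique(labels)) < 2L)
    stop("univariate selection needs both classes present", call. = FALSE)
  f_stat <- function(v) {
    g <- split(v, labels)
    n <- lengths(g); k <- length(g); N <- sum(n)
    gm <- mean(v)
    ssb <- sum(n * (vapply(g, mean, numeric(1)) - gm)^2)
    ssw <- sum(vapply(g, function(u) sum((u - mean(u))^2), numeric(1)))
    if (ssw == 0) return(if (ssb == 0) 0 else Inf)
    (ssb / (k - 1)) / (ssw / (N - k))
  }
  scores <- apply(deltas$values, 2L, f_stat)
  k <- ceiling(percentile * length(scores))
  ord <- order(-scores, colnames(deltas$values))
  keep <- sort(ord[seq_len(k)])
  out <- deltas
  out$values <- deltas$values[, keep, drop = FALSE]
  out
}

#' Rank-based AUC of scores against binary labels
#'
#' Area under the ROC curve computed as the normalised Mann-Whitney U
#' statistic: the probability that a random positive scores above a random
#' negative, ties counting one half.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (1/"allogenic" = positive).
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  pos <- labels == 1 | labels == "allogenic"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("need both classes to compute AUC",
                                 call. = FALSE)
  r <- rank(scores)
  u <- sum(r[pos]) - n1 * (n1 + 1) / 2
  u / (n1 * n0)
}

fit_gbm <- function(x, y, max_depth, eta, n_trees) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = eta, nthread = 1, seed = 42),
    data = dtrain, nrounds = n_trees, verbose = 0)
}

# stratified index sample: per class, a fixed fraction (at least one)
stratified_test_idx <- function(labels, fraction) {
  idx <- unlist(lapply(split(seq_along(labels), labels), function(i) {
    k <- max(1L, round(fraction * length(i)))
    sample(i, k)
  }), use.names = FALSE)
  sort(idx)
}

stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (i in split(seq_along(labels), labels))
    fold[i] <- sample(rep_len(seq_len(k), length(i)))
  fold
}

#' Stability-selection classification
#'
#' The core model-fitting procedure: the sample set is randomly re-partitioned
#' `n_shuffles` times into a stratified 80/20 train/test split; within each
#' training set the hyperparameters of a gradient-boosted tree ensemble are
#' tuned by stratified `cv_folds`-fold cross-validated AUC over `grid`; the
#' best candidate is refit on the whole training set with `n_trees` rounds
#' and scored on the held-out samples by rank-based AUC. The result
#' aggregates the per-shuffle AUCs (mean, SD) and the per-feature ensemble
#' importances (gain fractions, which sum to one within each shuffle)
#' averaged over shuffles.
#'
#' Feature filtering ([variance_filter()], [univariate_select()]) is applied
#' once, before the shuffles — pass either an already-filtered matrix or set
#' `filter = TRUE` to apply the config's thresholds here.
#'
#' @param deltas A `delta_matrix` (subjects x features with arm labels).
#' @param config An [ml_config()].
#' @param filter Apply the config's variance threshold and univariate
#'   selection before fitting (default `TRUE`).
#' @return An object of class `stability_fit`: `auc` (per-shuffle held-out
#'   AUCs), `mean_auc`, `sd_auc`, `importance` (named mean importance per
#'   surviving feature), `features`, `n_events` (re-drawn degenerate
#'   splits), `config`.
#' @export
stability_run <- function(deltas, config = ml_config(), filter = TRUE) {
  stopifnot(inherits(deltas, "delta_matrix"), inherits(config, "ml_config"))
  if (filter) {
    deltas <- variance_filter(deltas, config$variance_threshold)
    deltas <- univariate_select(deltas, config$select_percentile)
  }
  x <- deltas$values
  y <- as.integer(deltas$arm == "allogenic")
  if (length(unique(y)) < 2L)
    stop("both arms must be present", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))

  n_sh <- config$n_shuffles
  seeds <- derive_seeds(config$seed, 4L * n_sh)  # spares for re-draws
  grid <- config$grid
  auc <- numeric(n_sh)
  imp <- matrix(0, n_sh, ncol(x), dimnames = list(NULL, colnames(x)))
  n_events <- 0L
  next_seed <- n_sh

  for (s in seq_len(n_sh)) {
    seed_s <- seeds[s]
    repeat {
      split_ok <- with_seed(seed_s, {
        test_idx <- stratified_test_idx(y, config$test_fraction)
        train_idx <- setdiff(seq_along(y), test_idx)
        if (length(unique(y[train_idx])) < 2L ||
            length(unique(y[test_idx])) < 2L) NULL
        else list(train = train_idx, test = test_idx,
                  fold = stratified_folds(y[train_idx], config$cv_folds))
      })
      if (!is.null(split_ok)) break
      n_events <- n_events + 1L
      next_seed <- next_seed + 1L
      if (next_seed > length(seeds))
        stop("could not draw a two-class split", call. = FALSE)
      seed_s <- seeds[next_seed]
    }
    tr <- split_ok$train; te <- split_ok$test; fold <- split_ok$fold
    xtr <- x[tr, , drop = FALSE]; ytr <- y[tr]

    best <- 1L
    if (nrow(grid) > 1L) {
      cv_auc <- vapply(seq_len(nrow(grid)), function(g) {
        fold_auc <- vapply(seq_len(config$cv_folds), function(f) {
          hold <- fold == f
          if (length(unique(ytr[!hold])) < 2L ||
              length(unique(ytr[hold])) < 2L) return(NA_real_)
          m <- fit_gbm(xtr[!hold, , drop = FALSE], ytr[!hold],
                       grid$max_depth[g], grid$eta[g], config$n_trees)
          auc_rank(stats::predict(m, xtr[hold, , drop = FALSE]), ytr[hold])
        }, numeric(1))
        mean(fold_auc, na.rm = TRUE)
      }, numeric(1))
      best <- which.max(cv_auc)   # first max wins: deterministic tie-break
    }

    model <- fit_gbm(xtr, ytr, grid$max_depth[best], grid$eta[best],
                     config$n_trees)
    auc[s] <- auc_rank(stats::predict(model, x[te, , drop = FALSE]), y[te])
    it <- xgboost::xgb.importance(model = model)
    if (!is.null(it) && nrow(it)) imp[s, it$Feature] <- it$Gain
  }

  structure(list(auc = auc,
                 mean_auc = mean(auc),
                 sd_auc = stats::sd(auc),
                 importance = colMeans(imp),
                 importance_by_shuffle = imp,
                 features = colnames(x),
                 n_events = n_events,
                 config = config),
            class = "stability_fit")
}

#' @export
print.stability_fit <- function(x, ...) {
  cat(sprintf("stability_fit: %d shuffles, %d features\n",
              length(x$auc), length(x$features)))
  cat(sprintf("  mean held-out AUC %.3f (SD %.3f)\n", x$mean_auc, x$sd_auc))
  invisible(x)
}

#' @export
summary.stability_fit <- function(object, k = 10, ...) {
  cat(sprintf("Stability-selection classifier (%d shuffles, %d trees)\n",
              length(object$auc), object$config$n_trees))
  cat(sprintf("Held-out AUC: mean %.3f, SD %.3f, range [%.3f, %.3f]\n",
              object$mean_auc, object$sd_auc, min(object$auc), max(object$auc)))
  if (object$n_events)
    cat(sprintf("%d degenerate split(s) re-drawn\n", object$n_events))
  cat(sprintf("Top %d features by mean importance:\n",
              min(k, length(object$features))))
  print(utils::head(rank_importance(object, k), k))
  invisible(object)
}

#' @export
coef.stability_fit <- function(object, ...) object$importance

#' @export
plot.stability_fit <- function(x, k = 20, ...) {
  rk <- rank_importance(x, k)
  op <- graphics::par(mar = c(4, 9, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(rk$relative_pct), names.arg = rev(rk$feature),
                    horiz = TRUE, las = 1, cex.names = 0.7,
                    xlab = "relative importance (%)",
                    main = sprintf("mean AUC %.2f ± %.2f",
                                   x$mean_auc, x$sd_auc), ...)
  invisible(x)
}

#' Permutation significance of the classifier AUC
#'
#' Re-runs a (typically reduced-shuffle) [stability_run()] with the arm
#' labels permuted `n_perm` times and compares the observed mean held-out
#' AUC with the null distribution:
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)`.
#'
#' Because the univariate feature selection uses the arm labels, each
#' permutation re-applies the config's full filtering with the permuted
#' labels before fitting; this keeps the test valid (the selection bias
#' affects the observed and null statistics alike).
#'
#' @param deltas An unfiltered `delta_matrix` (filtering is applied inside,
#'   per iteration).
#' @param config `ml_config` for the observed run.
#' @param n_perm Number of label permutations (>= 19).
#' @param perm_config `ml_config` used inside each permutation; defaults to
#'   `config` with `n_shuffles` reduced to at most 5 and a single-point
#'   hyperparameter grid (no tuning), which keeps the null affordable.
#' @param observed Optionally a precomputed `stability_fit` for the
#'   unpermuted labels.
#' @param seed Seed for the permutation stream (default: `config$seed`).
#' @return Class `permutation_test`: `p_value`, `observed_auc`, `null_auc`.
#' @export
permutation_test <- function(deltas, config = ml_config(), n_perm = 999,
                             perm_config = NULL, observed = NULL,
                             seed = config$seed) {
  stopifnot(inherits(deltas, "delta_matrix"))
  if (n_perm < 19L) stop("n_perm must be >= 19", call. = FALSE)
  if (is.null(perm_config)) {
    perm_config <- config
    perm_config$n_shuffles <- min(config$n_shuffles, 5L)
    perm_config$grid <- config$grid[1L, , drop = FALSE]
  }
  if (is.null(observed)) observed <- stability_run(deltas, config)
  obs_auc <- observed$mean_auc

  perm_seeds <- derive_seeds(seed + 1L, n_perm)
  null_auc <- vapply(seq_len(n_perm), function(b) {
    dm <- deltas
    dm$arm <- with_seed(perm_seeds[b],
                        stats::setNames(sample(deltas$arm), names(deltas$arm)))
    cfg <- perm_config
    cfg$seed <- perm_seeds[b]
    stability_run(dm, cfg, filter = TRUE)$mean_auc
  }, numeric(1))

  p <- (1 + sum(null_auc >= obs_auc)) / (n_perm + 1)
  structure(list(p_value = p, observed_auc = obs_auc, null_auc = null_auc,
                 n_perm = n_perm),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("Permutation test: observed mean AUC %.3f, null mean %.3f over %d permutations\n",
              x$observed_auc, mean(x$null_auc), x$n_perm))
  cat(sprintf("  p = %.4g\n", x$p_value))
  invisible(x)
}

#' Rank features by mean importance
#'
#' Top-`k` features of a [stability_run()] by mean ensemble importance, with
#' the relative importance convention used throughout the reporting: the
#' most important feature is set to 100% and the rest are expressed relative
#' to it. Ties are broken by feature identifier.
#'
#' @param result A `stability_fit`.
#' @param k Number of features to report (default 20).
#' @return Data frame with `feature`, `importance`, `relative_pct`.
#' @export
rank_importance <- function(result, k = 20) {
  stopifnot(inherits(result, "stability_fit"))
  imp <- result$importance
  if (!length(imp)) stop("empty result", call. = FALSE)
  if (k > length(imp)) {
    warning("k exceeds the number of surviving features; returning all")
    k <- length(imp)
  }
  ord <- order(-imp, names(imp))
  top <- imp[ord[seq_len(k)]]
  mx <- max(imp)
  rel <- if (mx > 0) 100 * top / mx else rep(100, k)
  data.frame(feature = names(top), importance = unname(top),
             relative_pct = unname(rel), stringsAsFactors = FALSE)
}

#' Rescale values to a sub-unit interval
#'
#' Affine map sending the minimum to `lo` and the maximum to `hi`
#' (defaults 0.1 and 1.0), the convention used for spider-plot displays of
#' relative delta differences.
#'
#' @param values Numeric vector with at least two distinct values.
#' @param lo,hi Target endpoints.
#' @return Rescaled vector; a constant input maps to the midpoint with a
#'   warning.
#' @export
#' @examples
#' rescale_unit_interval(c(0, 5, 10))  # 0.10 0.55 1.00
rescale_unit_interval <- function(values, lo = 0.1, hi = 1.0) {
  rng <- range(values, finite = TRUE)
  if (rng[1] == rng[2]) {
    warning("constant input: returning the midpoint")
    return(rep((lo + hi) / 2, length(values)))
  }
  lo + (values - rng[1]) / (rng[2] - rng[1]) * (hi - lo)
}
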