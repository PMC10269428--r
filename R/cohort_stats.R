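#' Two-sample t-test from summary statistics
#'
#' Recomputes a two-sample t-test from printed group summaries
#' (n, mean, SD), as needed to reproduce baseline-characteristics tables
#' where only summaries are published. Both the pooled-variance and the
#' Welch (unequal-variance) forms are available; Welch is the default.
#'
#' @param g1,g2 Named numeric vectors (or lists) with elements `n`, `mean`,
#'   `sd`.
#' @param variant `"welch"` or `"pooled"`.
#' @return An object of class `htest` with the t statistic, degrees of
#'   freedom and two-sided p-value.
#' @export
#' @examples
#' ttest_from_summary(c(n = 11, mean = 48.5, sd = 10.2),
#'                    c(n = 10, mean = 51.2, sd = 6.6))
ttest_from_summary <- function(g1, g2, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  g1 <- as.list(g1); g2 <- as.list(g2)
  for (g in list(g1, g2)) {
    if (!all(c("n", "mean", "sd") %in% names(g)))
      stop("group summaries need n, mean, sd", call. = FALSE)
    if (g$n < 2) stop("each group needs n >= 2", call. = FALSE)
    if (g$sd < 0) stop("sd must be >= 0", call. = FALSE)
  }
  n1 <- g1$n; m1 <- g1$mean; s1 <- g1$sd
  n2 <- g2$n; m2 <- g2$mean; s2 <- g2$sd
  if (s1 == 0 && s2 == 0) {
    tstat <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
    df <- n1 + n2 - 2
    p <- if (m1 == m2) 1 else 0
  } else if (variant == "pooled") {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    p <- 2 * stats::pt(-abs(tstat), df)
  } else {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    tstat <- (m1 - m2) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
  }
  structure(list(statistic = c(t = tstat), parameter = c(df = df),
                 p.value = p,
                 method = sprintf("Two-sample t-test from summaries (%s)",
                                  variant),
                 data.name = "group summaries"),
            class = "htest")
}

#' Mann-Whitney U test
#'
#' Rank-sum test for a location shift between two samples. For small
#' tie-free samples (`n1 + n2 <= 12`) the two-sided p-value is exact, by
#' enumeration of all assignments of the pooled ranks to the first group;
#' otherwise a normal approximation with tie and continuity corrections is
#' used. The exact p is the null probability of a U at least as far from
#' its mean `n1 n2 / 2` as observed.
#'
#' @param x,y Numeric vectors (nonempty).
#' @param exact Force (`TRUE`) or forbid (`FALSE`) enumeration; default
#'   `NULL` chooses automatically.
#' @return An `htest` with the U statistic and two-sided p-value.
#' @export
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
mann_whitney <- function(x, y, exact = NULL) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y))
    stop("both samples must be nonempty", call. = FALSE)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(pooled))
  do_exact <- exact %||% (n <= 12L && !ties)
  if (do_exact && ties)
    stop("exact enumeration is not defined with ties", call. = FALSE)

  if (do_exact) {
    # enumerate all C(n, n1) rank assignments to the first group
    combos <- utils::combn(n, n1)
    rsum <- colSums(matrix(seq_len(n)[combos], nrow = n1))
    u_null <- rsum - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    p <- mean(abs(u_null - mu) >= abs(u - mu) - 1e-9)
    method <- "Mann-Whitney U test (exact, enumeration)"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "Mann-Whitney U test (normal approximation, tie-corrected)"
  }
  structure(list(statistic = c(U = u), p.value = p, method = method,
                 data.name = "x and y"),
            class = "htest")
}

#' Exact Fisher-Freeman-Halton test for r x c tables
#'
#' Exact test of independence in an r x c contingency table by full
#' enumeration. Every table with the observed row and column margins is
#' generated recursively; each has multivariate hypergeometric probability
#' `prod(row!) prod(col!) / (N! prod(cell!))`. The two-sided p-value sums
#' the probabilities of all tables no more probable than the observed one
#' (relative tolerance 1e-7 on floating-point ties). For 2 x 2 tables this
#' reduces to the classical hypergeometric two-sided Fisher test.
#'
#' @param tab Matrix of nonnegative integer counts, at least 2 x 2.
#' @param budget Maximum number of tables to enumerate (error beyond).
#' @return An `htest` with `p.value`, the observed table probability as the
#'   statistic, and `n.tables` / `prob.total` in the `enumeration` element.
#' @export
#' @examples
#' fisher_exact_rxc(matrix(c(10, 1, 7, 3), 2))  # sex by arm
fisher_exact_rxc <- function(tab, budget = 1e7) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("table must be at least 2 x 2", call. = FALSE)
  if (sum(tab) == 0) stop("table has no observations", call. = FALSE)
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)

  log_const <- sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(n)
  logp_of <- function(cells) log_const - sum(lfactorial(cells))
  logp_obs <- logp_of(tab)

  env <- new.env(parent = emptyenv())
  env$p_le <- 0; env$p_tot <- 0; env$count <- 0
  thresh <- logp_obs + log1p(1e-7)

  r <- nrow(tab); cc <- ncol(tab)
  # fill row by row; inside a row, cell by cell, bounded by what the
  # column margins still allow
  recurse_row <- function(i, col_rem, cells_so_far) {
    if (i == r) {        # last row forced by remaining column margins
      env$count <- env$count + 1
      if (env$count > budget)
        stop("enumeration budget exceeded (", format(budget, scientific = FALSE),
             " tables); consider a Monte Carlo approach", call. = FALSE)
      lp <- log_const - cells_so_far - sum(lfactorial(col_rem))
      p <- exp(lp)
      env$p_tot <- env$p_tot + p
      if (lp <= thresh) env$p_le <- env$p_le + p
      return(invisible())
    }
    fill_cell <- function(j, row_rem, col_rem, acc) {
      if (j == cc) {     # last cell of the row forced by the row margin
        if (row_rem > col_rem[cc]) return(invisible())
        col_rem[cc] <- col_rem[cc] - row_rem
        recurse_row(i + 1L, col_rem, acc + lfactorial(row_rem))
        return(invisible())
      }
      # x_ij can be 0..min(row_rem, col margin), but must leave enough
      # room in the later columns to absorb the rest of the row
      later <- sum(col_rem[(j + 1L):cc])
      lo <- max(0L, row_rem - later)
      hi <- min(row_rem, col_rem[j])
      if (lo > hi) return(invisible())
      for (x in lo:hi) {
        col2 <- col_rem; col2[j] <- col2[j] - x
        fill_cell(j + 1L, row_rem - x, col2, acc + lfactorial(x))
      }
    }
    fill_cell(1L, rs[i], col_rem, cells_so_far)
  }
  recurse_row(1L, cs, 0)

  structure(list(statistic = c("P(observed)" = exp(logp_obs)),
                 p.value = min(1, env$p_le),
                 method = "Fisher-Freeman-Halton exact test (full enumeration)",
                 data.name = sprintf("%d x %d table, N = %d", r, cc, n),
                 enumeration = list(n.tables = env$count,
                                    prob.total = env$p_tot)),
            class = "htest")
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' Pearson correlation of average ranks; two-sided p from
#' `t = rho sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Paired numeric vectors, `n >= 3` complete pairs.
#' @return List with `rho`, `p`, `n`. A constant input yields `rho = NA`
#'   with a warning.
#' @export
#' @examples
#' spearman_rank(c(1, 2, 3), c(3, 1, 2))  # rho = -0.5
spearman_rank <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Spearman rho undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Correlate methylation features with histology scores
#'
#' Spearman correlation of every (CpG, histology score) pair, e.g. baseline
#' beta values or methylation deltas against ordinal severity scores
#' (steatosis %, NAS, necro-inflammation, fibrosis, ballooning). Rows are
#' sorted by decreasing `|rho|`.
#'
#' @param cpgs A `delta_matrix`, or a numeric matrix with subjects as rows
#'   and CpGs as columns.
#' @param histology Data frame with `subject_id` and one column per score.
#' @param scores Score columns to use (default: all non-id columns).
#' @return Data frame with columns `cpg`, `score`, `rho`, `p`.
#' @export
correlate_histology <- function(cpgs, histology, scores = NULL) {
  m <- if (inherits(cpgs, "delta_matrix")) cpgs$values else cpgs
  stopifnot(is.matrix(m))
  scores <- scores %||% setdiff(names(histology), "subject_id")
  common <- intersect(rownames(m), histology$subject_id)
  if (!length(common))
    stop("no overlapping subjects between methylation and histology",
         call. = FALSE)
  m <- m[common, , drop = FALSE]
  h <- histology[match(common, histology$subject_id), , drop = FALSE]
  out <- expand.grid(cpg = colnames(m), score = scores,
                     stringsAsFactors = FALSE)
  res <- mapply(function(cg, sc) {
    r <- suppressWarnings(spearman_rank(m[, cg], h[[sc]]))
    c(r$rho, r$p)
  }, out$cpg, out$score)
  out$rho <- res[1L, ]
  out$p <- res[2L, ]
  out <- out[order(-abs(out$rho), out$cpg, out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}
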