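test_that("summary t-tests match a raw-data t-test oracle", {
  x <- with_seed(1, rnorm(11, 5, 2))
  y <- with_seed(2, rnorm(10, 6, 1.5))
  gx <- c(n = 11, mean = mean(x), sd = sd(x))
  gy <- c(n = 10, mean = mean(y), sd = sd(y))
  pooled <- ttest_from_summary(gx, gy, "pooled")
  welch <- ttest_from_summary(gx, gy, "welch")
  expect_equal(pooled$p.value, t.test(x, y, var.equal = TRUE)$p.value,
               tolerance = 1e-12)
  expect_equal(welch$p.value, t.test(x, y)$p.value, tolerance = 1e-12)
  expect_equal(unname(welch$statistic), unname(t.test(x, y)$statistic),
               tolerance = 1e-12)
})

test_that("degenerate and symmetric summaries behave", {
  g <- c(n = 10, mean = 3, sd = 1)
  same <- ttest_from_summary(g, g)
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)
  flat <- ttest_from_summary(c(n = 5, mean = 2, sd = 0),
                             c(n = 5, mean = 2, sd = 0))
  expect_equal(flat$p.value, 1)
  expect_equal(unname(flat$statistic), 0)
})

test_that("exact Mann-Whitney enumerates the null distribution", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(unname(mw$statistic), 0)
  expect_equal(mw$p.value, 1 / 3)
  # oracle: exact wilcox.test on tie-free data
  for (seed in 1:10) {
    x <- with_seed(seed, rnorm(5))
    y <- with_seed(seed + 100, rnorm(6))
    expect_equal(mann_whitney(x, y)$p.value,
                 wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("the normal approximation tracks the exact Mann-Whitney p", {
  # identical multisets: no shift, approximate p near 1
  x <- c(1, 2, 3, 4)
  expect_gte(mann_whitney(x, x, exact = FALSE)$p.value, 0.99)
  for (seed in 1:10) {
    x <- with_seed(seed, rnorm(6))
    y <- with_seed(seed + 50, rnorm(6))
    expect_lt(abs(mann_whitney(x, y, exact = TRUE)$p.value -
                    mann_whitney(x, y, exact = FALSE)$p.value), 0.05)
  }
  expect_error(mann_whitney(numeric(0), 1:3), "nonempty")
})

test_that("enumerated table probabilities form a distribution", {
  for (seed in 1:50) {
    tab <- with_seed(seed, {
      r <- sample(2:4, 1); cc <- sample(2:4, 1)
      matrix(rmultinom(1, sample(8:25, 1), rep(1, r * cc)), r, cc)
    })
    if (sum(tab) == 0) next
    res <- fisher_exact_rxc(tab)
    expect_equal(res$enumeration$prob.total, 1, tolerance = 1e-9)
    expect_gte(res$p.value, 0)
    expect_lte(res$p.value, 1)
  }
})

test_that("2x2 enumeration equals the closed-form hypergeometric test", {
  for (seed in 1:50) {
    tab <- with_seed(seed, matrix(rpois(4, 4), 2, 2))
    if (sum(tab) == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      tab <- tab + 1
    expect_equal(fisher_exact_rxc(tab)$p.value,
                 fisher.test(tab)$p.value, tolerance = 1e-9)
  }
  # all tables as likely as the observed one: p = 1
  expect_equal(fisher_exact_rxc(matrix(c(2, 1, 1, 2), 2))$p.value, 1)
})

test_that("r x c enumeration matches the exact oracle on small tables", {
  tabs <- list(matrix(c(1, 0, 10, 6, 0, 4), 3, byrow = TRUE),
               matrix(c(3, 2, 6, 5, 2, 2, 0, 1), 4, byrow = TRUE),
               matrix(c(2, 3, 1, 4, 0, 5), 2, byrow = TRUE))
  for (tab in tabs)
    expect_equal(fisher_exact_rxc(tab)$p.value, fisher.test(tab)$p.value,
                 tolerance = 1e-7)
  expect_error(fisher_exact_rxc(matrix(c(50, 40, 45, 60, 55, 38), 2),
                                budget = 100), "budget")
})

test_that("Spearman correlation honours rank invariance", {
  x <- c(0.3, 1.5, 2.2, 5.1, 9.0)
  expect_equal(spearman_rank(x, exp(x))$rho, 1)
  expect_equal(spearman_rank(x, -x)$rho, -1)
  expect_equal(spearman_rank(c(1, 2, 3), c(3, 1, 2))$rho, -0.5)
  # symmetry and oracle agreement
  y <- with_seed(3, rnorm(12))
  z <- with_seed(4, rnorm(12))
  a <- spearman_rank(y, z); b <- spearman_rank(z, y)
  expect_equal(a$rho, b$rho)
  ct <- suppressWarnings(cor.test(y, z, method = "spearman"))
  expect_equal(a$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_warning(spearman_rank(rep(1, 5), 1:5), "constant")
})

test_that("histology correlations recover a planted CpG association", {
  coh <- generate_cohort(cohort_config(n_species = 5, n_metabolites = 5,
                                       n_cpgs = 60, seed = 21))
  md <- coh$metadata
  base <- md$sample_id[md$timepoint_weeks == 0]
  m <- t(coh$methylome$values[, base])
  rownames(m) <- md$subject_id[match(base, md$sample_id)]
  res <- correlate_histology(m, coh$histology, scores = "ballooning")
  expect_equal(nrow(res), 60L)                       # one row per CpG
  expect_equal(res$cpg[1], coh$truth$histology_cpg)  # top |rho| is the plant
  expect_true(all(diff(abs(res$rho)) <= 1e-12))      # sorted by |rho|
})

test_that("histology correlations on noise look like the null", {
  coh <- generate_cohort(cohort_config(n_species = 5, n_metabolites = 5,
                                       n_cpgs = 50, seed = 33))
  dm <- suppressMessages(cohort_deltas(coh, "methylome", curate = FALSE))
  res <- correlate_histology(dm, coh$histology, scores = "nas")
  expect_lt(median(abs(res$rho)), 0.5)
  bad <- coh$histology; bad$subject_id <- paste0("Z", bad$subject_id)
  expect_error(correlate_histology(dm, bad), "overlapping")
})
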