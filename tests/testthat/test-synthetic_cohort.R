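test_that("the same seed reproduces the cohort bit for bit", {
  a <- tiny_cohort(seed = 7)
  b <- tiny_cohort(seed = 7)
  expect_identical(a$microbiome$values, b$microbiome$values)
  expect_identical(a$metabolome$values, b$metabolome$values)
  expect_identical(a$methylome$values, b$methylome$values)
  expect_identical(a$histology, b$histology)
  expect_identical(a$truth, b$truth)
  c <- tiny_cohort(seed = 8)
  expect_false(identical(a$microbiome$values, c$microbiome$values))
})

test_that("default arm sizes give 10 + 11 subjects over two timepoints", {
  coh <- generate_cohort(cohort_config(n_species = 10, n_metabolites = 10,
                                       n_cpgs = 10, seed = 1))
  md <- coh$metadata
  expect_equal(nrow(md), 42L)
  arm_by_subject <- unique(md[, c("subject_id", "arm")])
  expect_equal(sum(arm_by_subject$arm == "allogenic"), 10L)
  expect_equal(sum(arm_by_subject$arm == "autologous"), 11L)
  # every subject appears at exactly both timepoints
  tp <- table(md$subject_id, md$timepoint_weeks)
  expect_true(all(tp == 1L))
})

test_that("modality value ranges and compositional closure hold", {
  coh <- tiny_cohort(seed = 3)
  expect_true(all(abs(colSums(coh$microbiome$values) - 1) < 1e-9))
  expect_true(all(coh$methylome$values >= 0 & coh$methylome$values <= 1))
  expect_true(all(coh$metabolome$values > 0, na.rm = TRUE))
  # planted truth refers to real features
  for (m in c("microbiome", "metabolome", "methylome"))
    expect_true(all(coh$truth$planted[[m]] %in% rownames(coh[[m]]$values)))
  expect_true(all(unlist(coh$truth$modules[, -1]) %in%
                    unlist(lapply(coh[c("microbiome", "metabolome", "methylome")],
                                  function(t) rownames(t$values)))))
})

test_that("metabolite missingness approximates the configured censoring rate", {
  coh <- generate_cohort(cohort_config(n_metabolites = 200, n_species = 5,
                                       n_cpgs = 5, missing_rate = 0.2,
                                       seed = 11))
  frac <- mean(!is.finite(coh$metabolome$values))
  expect_gt(frac, 0.12)
  expect_lt(frac, 0.25)
  none <- generate_cohort(cohort_config(n_metabolites = 50, n_species = 5,
                                        n_cpgs = 5, missing_rate = 0,
                                        seed = 11))
  expect_false(anyNA(none$metabolome$values))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_planted_per_modality = 50, n_species = 10),
               "exceeds")
  expect_error(cohort_config(missing_rate = 1), "missing_rate")
  expect_error(cohort_config(effect_size = -1), "effect_size")
  expect_error(cohort_config(n_cross_modules = 9, n_planted_per_modality = 5),
               "n_cross_modules")
})

test_that("cohorts round-trip losslessly through the TSV writers", {
  coh <- tiny_cohort(seed = 5)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  for (m in c("microbiome", "metabolome", "methylome"))
    expect_equal(back[[m]]$values, coh[[m]]$values, tolerance = 1e-12)
  expect_equal(back$metadata, coh$metadata)
  expect_equal(back$histology, coh$histology)
  expect_equal(back$methylome$annotations$maf, coh$methylome$annotations$maf)
})

test_that("a zero-feature cohort writes valid headers and no rows", {
  coh <- generate_cohort(cohort_config(n_species = 0, n_metabolites = 0,
                                       n_cpgs = 0, n_planted_per_modality = 0,
                                       n_cross_modules = 0, seed = 1))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  lines <- readLines(file.path(dir, "microbiome.tsv"))
  expect_equal(length(lines), 1L)
  expect_match(lines[1], "^feature_id\t")
  back <- read_cohort(dir)
  expect_equal(nrow(back$microbiome$values), 0L)
})

test_that("increasing the planted effect does not decrease downstream AUC", {
  mean_auc_at <- function(effect) {
    mean(vapply(1:5, function(seed) {
      coh <- generate_cohort(cohort_config(n_species = 60, n_metabolites = 10,
                                           n_cpgs = 10, effect_size = effect,
                                           n_cross_modules = 0, seed = seed))
      dm <- cohort_deltas(coh, "microbiome")
      stability_run(dm, fast_config(seed = seed))$mean_auc
    }, numeric(1)))
  }
  expect_gt(mean_auc_at(1.5), mean_auc_at(0))
})

test_that("arms are exchangeable when no effect is planted", {
  # per seed: no feature separates the arms after Bonferroni correction
  clean <- vapply(1:20, function(seed) {
    coh <- generate_cohort(cohort_config(n_species = 50, n_metabolites = 5,
                                         n_cpgs = 5, effect_size = 0,
                                         n_cross_modules = 0, seed = seed))
    dm <- cohort_deltas(coh, "microbiome")
    p <- apply(dm$values, 2, function(v)
      stats::t.test(v[dm$arm == "allogenic"],
                    v[dm$arm == "autologous"])$p.value)
    min(stats::p.adjust(p, "bonferroni")) > 0.05
  }, logical(1))
  expect_gte(mean(clean), 0.95)
})
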