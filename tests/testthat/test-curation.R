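test_that("metabolite curation imputes the detection floor then scales medians to one", {
  v <- matrix(c(2, 4, NA), 1, dimnames = list("m1", c("a", "b", "c")))
  out <- curate_metabolites(toy_metabolome(v))
  expect_equal(unname(out$table$values[1, ]), c(1, 2, 1))

  # all-equal finite values become exactly 1 after median scaling
  v2 <- matrix(7, 3, 4, dimnames = list(paste0("m", 1:3), paste0("s", 1:4)))
  out2 <- curate_metabolites(toy_metabolome(v2))
  expect_true(all(out2$table$values == 1))

  # every retained metabolite has median exactly 1
  w <- with_seed(1, matrix(exp(rnorm(50 * 8)), 50, 8,
                           dimnames = list(paste0("m", 1:50), paste0("s", 1:8))))
  w[with_seed(2, sample(length(w), 40))] <- NA
  out3 <- curate_metabolites(toy_metabolome(w))
  expect_equal(unname(apply(out3$table$values, 1, stats::median)),
               rep(1, nrow(out3$table$values)))
})

test_that("unknown metabolites and xenobiotics are removed and counted", {
  v <- matrix(1:20, 5, 4,
              dimnames = list(paste0("m", 1:5), paste0("s", 1:4)))
  tab <- toy_metabolome(v,
                        identified = c(FALSE, FALSE, TRUE, TRUE, TRUE),
                        pathway = c("Lipid", "Xenobiotics", "Xenobiotics",
                                    "Lipid", "Amino Acid"))
  out <- curate_metabolites(tab)
  expect_equal(nrow(out$table$values), 2L)
  expect_equal(sort(rownames(out$table$values)), c("m4", "m5"))
  expect_equal(out$report$n_in, 5L)
  expect_equal(out$report$n_out, 2L)
  expect_equal(unname(out$report$counts[["unknown_metabolite"]]), 2L)
  expect_equal(unname(out$report$counts[["xenobiotic"]]), 1L)
  # unknown takes precedence for m2 (unknown AND xenobiotic)
  expect_equal(unname(out$report$reasons[["m2"]]), "unknown_metabolite")
})

test_that("a metabolite with no finite value is excluded with its reason", {
  v <- matrix(c(1, 2, NA, NA), 2, byrow = TRUE,
              dimnames = list(c("m1", "m2"), c("s1", "s2")))
  out <- curate_metabolites(toy_metabolome(v))
  expect_equal(rownames(out$table$values), "m1")
  expect_equal(unname(out$report$reasons[["m2"]]), "all_missing")
  expect_equal(out$report$n_in - out$report$n_excluded, out$report$n_out)
})

test_that("gap signals are found by the sorted-gap rule", {
  g <- gaphunt(c(0.10, 0.12, 0.50, 0.52, 0.90), 0.20)
  expect_equal(g$cluster_count, 3L)
  expect_true(g$flagged)
  expect_equal(gaphunt(rep(0.4, 5))$cluster_count, 1L)
  expect_false(gaphunt(rep(0.4, 5))$flagged)
  # exactly two clusters is not flagged: the rule is strictly > 2
  g2 <- gaphunt(c(0.1, 0.9))
  expect_equal(g2$cluster_count, 2L)
  expect_false(g2$flagged)
  expect_error(gaphunt(0.5), "two finite values")
  # cluster count is invariant under permutation of the input
  v <- c(0.05, 0.1, 0.45, 0.5, 0.85, 0.9)
  for (i in 1:5) {
    perm <- with_seed(i, sample(v))
    expect_equal(gaphunt(perm)$cluster_count, gaphunt(v)$cluster_count)
  }
})

test_that("probe exclusion applies each rule with fixed precedence", {
  tab <- toy_methylome(
    n_probes = 6,
    chrom = c("chrX", "chrY", "chr2", "chr3", "chr4", "chr5"),
    maf = c(0.5, 0, 0, 0.02, 0.005, 0),
    promiscuous = c(1L, 0L, 1L, 0L, 0L, 0L))
  out <- filter_probes(tab)
  r <- out$report$reasons
  expect_equal(unname(r[["cg00001"]]), "allosome")   # chrX wins over maf+prom
  expect_equal(unname(r[["cg00002"]]), "allosome")
  expect_equal(unname(r[["cg00003"]]), "promiscuous")
  expect_equal(unname(r[["cg00004"]]), "snp_maf")    # maf 0.02 > 1%
  expect_equal(sort(rownames(out$table$values)), c("cg00005", "cg00006"))
  # maf 0.005 retained: the cutoff is strictly > 0.01
  expect_false("cg00005" %in% names(r))
})

test_that("gap-signal probes are excluded and filtering is idempotent", {
  # 100 probes, 10 planted violations: 4 allosome, 3 promiscuous, 2 snp, 1 gap
  n <- 100
  chrom <- rep("chr1", n); chrom[1:4] <- c("chrX", "chrX", "chrY", "chrX")
  prom <- rep(0L, n); prom[5:7] <- 1L
  maf <- rep(0, n); maf[8:9] <- c(0.05, 0.3)
  betas <- with_seed(9, matrix(runif(n * 10, 0.40, 0.60), n, 10))
  betas[10, ] <- rep(c(0.05, 0.5, 0.95), length.out = 10)  # 3 clusters
  tab <- toy_methylome(n_probes = n, n_samples = 10, chrom = chrom,
                       maf = maf, promiscuous = prom, betas = betas)
  out <- filter_probes(tab)
  expect_equal(out$report$n_out, 90L)
  expect_equal(unname(out$report$counts[["allosome"]]), 4L)
  expect_equal(unname(out$report$counts[["promiscuous"]]), 3L)
  expect_equal(unname(out$report$counts[["snp_maf"]]), 2L)
  expect_equal(unname(out$report$counts[["gap_signal"]]), 1L)
  again <- filter_probes(out$table)
  expect_identical(again$table$values, out$table$values)
  expect_equal(again$report$n_excluded, 0L)
})

test_that("probes missing from the manifest are reported by name", {
  tab <- toy_methylome(n_probes = 3)
  tab$annotations <- tab$annotations[-2, ]
  expect_error(filter_probes(tab), "cg00002")
})

test_that("CPM normalisation scales each sample to one million", {
  expect_equal(cpm_normalize(c(1, 3)), c(250000, 750000))
  expect_equal(cpm_normalize(c(1e6, 0)), c(1e6, 0))
  m <- with_seed(4, matrix(rexp(30), 5, 6))
  out <- cpm_normalize(m)
  expect_equal(unname(colSums(out)), rep(1e6, 6), tolerance = 1e-12)
  expect_error(cpm_normalize(c(0, 0)), "all-zero")
})

test_that("deltas are relative changes with a per-feature floor", {
  before <- matrix(c(2, 0), 2, 3, dimnames = list(c("f1", "f2"), NULL))
  after <- matrix(c(3, 0.2), 2, 3, dimnames = list(c("f1", "f2"), NULL))
  # give f2 a positive value somewhere so its floor is 0.1
  before[2, 2] <- 0.1; after[2, 2] <- 0.1
  tp <- toy_pair(before, after)
  dm <- compute_delta(tp$before, tp$after, tp$metadata)
  expect_equal(unname(dm$values[1, "f1"]), 0.5)           # (3-2)/2
  expect_equal(unname(dm$values[1, "f2"]), 2.0)           # (0.2-0)/0.1
  expect_true(all(is.finite(dm$values)))
  # identical timepoints give the zero matrix
  dm0 <- compute_delta(tp$before, tp$before, tp$metadata)
  expect_true(all(dm0$values == 0))
})

test_that("unpaired subjects are dropped and reported", {
  before <- matrix(1:6, 2, 3, dimnames = list(c("f1", "f2"), NULL))
  after <- matrix(2:7, 2, 3, dimnames = list(c("f1", "f2"), NULL))
  tp <- toy_pair(before, after)
  # remove one follow-up sample
  after_cut <- subset_omics(tp$after, samples = colnames(tp$after$values)[-1])
  expect_message(dm <- compute_delta(tp$before, after_cut, tp$metadata),
                 "P1")
  expect_equal(nrow(dm$values), 2L)
  expect_equal(dm$dropped, "P1")
  # no overlap at all errors
  md_bad <- tp$metadata
  md_bad$subject_id <- paste0(md_bad$subject_id,
                              rep(c("x", "y"), each = nrow(md_bad) / 2))
  expect_error(compute_delta(tp$before, tp$after, md_bad), "no subjects")
})
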