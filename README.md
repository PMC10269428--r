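# fmtomics

Multi-omics stability-selection analysis for small paired two-arm FMT
(faecal microbiota transplantation) cohorts.

## The problem

Paired FMT trials in fatty-liver disease are tiny — here 21 subjects (10
allogenic-donor, 11 autologous-control), profiled at baseline and 24
weeks across three omics layers: species-level metagenomic relative
abundances, untargeted plasma metabolite intensities (Metabolon-style),
and liver DNA methylation beta values (EPIC-array-style). The scientific
question is whether the *changes* between the two timepoints distinguish
donor FMT from control, and which microbial, metabolic and epigenetic
features carry that signal, jointly.

`fmtomics` implements that analysis as a tested, fully reproducible
pipeline for R users working on paired multi-omics intervention cohorts:

* **Curation** — metabolite curation (unknowns and xenobiotics removed,
  below-detection values imputed at the per-metabolite minimum, medians
  scaled to 1), EPIC probe exclusion (allosomes, cross-reactive probes,
  SNPs with MAF > 1%, multi-modal "gap signal" probes), and
  copies-per-million normalisation.
* **Delta features** — per-subject relative changes
  `(after − before) / max(|before|, ε_f)` with a per-feature positive
  floor `ε_f`.
* **Stability-selection classifier** — per modality: unsupervised
  variance threshold, univariate ANOVA-F selection, then 100 random
  stratified 80/20 train/test partitions of a gradient-boosted tree
  ensemble (2000 trees, hyperparameters tuned by 3-fold CV inside each
  training set). Performance is the mean ± SD held-out AUC, defined as
  the rank statistic `U / (n₁n₀)`; feature importances (gain fractions,
  summing to 1 per partition) are averaged across partitions, with the
  top feature reported as 100%.
* **Permutation significance** — `p = (1 + #{null ≥ observed})/(B + 1)`
  with the *entire* pipeline (including the label-using feature
  selection) re-run per permutation.
* **Cross-omics network** — Spearman correlations of the delta values of
  each modality's top-20 features; edges kept at |ρ| ≥ 0.6; exported as
  edge-list TSV and GraphML.
* **Baseline statistics** — two-sample t-tests recomputable from
  printed (n, mean, SD) summaries, exact Mann-Whitney U by enumeration,
  and an exact Fisher-Freeman-Halton r×c test by full enumeration of
  margin-constrained tables.
* **Synthetic cohort generator** — a compositional / log-normal /
  logit-normal paired cohort with planted arm-by-time effects and
  cross-omics correlated modules, so every stage is testable without
  access to patient-level (controlled-access) data.

## Worked example

```r
library(fmtomics)

coh <- generate_cohort(cohort_config(seed = 11, effect_size = 1.5))
coh
#> Synthetic paired FMT cohort: 10 allogenic + 11 autologous subjects, 42 samples
#>   microbiome 120 species | metabolome 200 metabolites | methylome 300 CpGs
#>   planted: 5 features/modality (effect size 1.50), 2 cross-omics module(s)

dm  <- cohort_deltas(coh, "microbiome")   # curate + paired relative changes
cfg <- ml_config(variance_threshold = 0.01, select_percentile = 0.35,
                 n_shuffles = 25, n_trees = 200, seed = 11)
fit <- stability_run(dm, cfg)
fit
#> stability_fit: 25 shuffles, 42 features
#>   mean held-out AUC 0.950 (SD 0.102)

head(rank_importance(fit, 20), 3)
#>   feature importance relative_pct
#> 1  sp_063 0.75871815   100.000000
#> 2  sp_108 0.07683829    10.127382
#> 3  sp_022 0.07109133     9.369927

permutation_test(dm, cfg, n_perm = 99, observed = fit)
#> Permutation test: observed mean AUC 0.950, null mean 0.583 over 99 permutations
#>   p = 0.04
```

The mean AUC of 0.95 says the ensemble separates the arms almost
perfectly on held-out subjects of this planted-effect cohort; the two
top-ranked species (`sp_063`, `sp_108`) are indeed planted
discriminative features (`coh$truth$planted$microbiome`), and the
permutation p of 0.04 is the calibrated statement that such a mean AUC
is unlikely under label exchangeability — at 99 permutations the
smallest attainable p is 0.01.

Baseline-characteristics tests work straight from published summaries —
e.g. ALT (IU/L), 48.1 ± 16.5 (n = 11) vs 70.8 ± 23.4 (n = 10):

```r
ttest_from_summary(c(n = 11, mean = 48.1, sd = 16.5),
                   c(n = 10, mean = 70.8, sd = 23.4))
#> 	Two-sample t-test from summaries (welch)
#> t = -2.5458, df = 16.028, p-value = 0.02156

fisher_exact_rxc(matrix(c(10, 1, 7, 3), 2))$p.value   # sex by arm
#> [1] 0.3107769
```

The full pipeline (`run_pipeline(pipeline_config(...))`) chains
simulate/load → curate → deltas → classify (+ permutation) → rank →
network → histology correlations and writes a JSON report, ranked
feature tables, per-shuffle AUCs and the GraphML network.

## Documentation

The methods vignette (`vignettes/fmtomics-methods.Rmd`) describes the
model and its assumptions, every tunable parameter with its default and
rationale, what the synthetic generator does and does not emulate, and
the package's numerical conventions.
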