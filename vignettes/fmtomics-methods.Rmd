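---
title: "Methods: multi-omics stability-selection analysis for paired FMT cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics stability-selection analysis for paired FMT cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`fmtomics` implements the analysis skeleton of a small paired two-arm
faecal microbiota transplantation (FMT) study: 21 subjects (10 receiving
donor, "allogenic", FMT; 11 receiving their own, "autologous", stool as
control), each profiled at baseline and at 24 weeks across three omics
layers — species-level metagenomic relative abundances, untargeted plasma
metabolite intensities, and liver DNA methylation beta values. The package
covers curation, paired delta features, a stability-selection classifier
with permutation significance, feature ranking, a cross-omics Spearman
network, baseline statistics, and a synthetic cohort generator used to
validate every stage. Raw-data processing (read QC, taxonomic profiling,
array normalisation, mass-spectrometry acquisition) is out of scope: the
package starts from feature-by-sample tables.

# Curation

**Metabolites** (`curate_metabolites`). Chemically unidentified compounds
are removed first, then xenobiotics (exogenous compounds, identified by
their super-pathway annotation). Missing intensities are treated as
below-detection and imputed with the metabolite's lowest measured raw
value — the observed detection floor — and each metabolite is then scaled
so its median is exactly 1. Imputation precedes scaling deliberately: the
imputed value is a physical floor on the raw scale, and scaling first
would distort it. A metabolite with no finite value has no floor and is
excluded (reason `all_missing`).

**Methylation probes** (`filter_probes`). Four standard EPIC-array
exclusions, applied in a fixed order so each probe gets a deterministic
first-matching reason: allosomal probes (chrX/chrY; the cohort is
mixed-sex), cross-reactive ("promiscuous") probes per a manifest flag,
probes overlapping a SNP with minor allele frequency above 1% per the
manifest, and probes with a gap signal. The gap rule (`gaphunt`) sorts a
probe's beta values and starts a new cluster wherever consecutive values
differ by more than 0.20 on the beta scale; more than two clusters flags
the probe, since multi-modal beta distributions usually reflect underlying
genotype rather than epigenetic state. This is the sorted-gap core of the
rule; the outlier-group bookkeeping some array toolkits add on top is
intentionally not replicated. Cross-reactive probes are taken from the
manifest flag rather than recomputed from sequence, since published
blacklists are the accepted source.

**Abundances** (`cpm_normalize`). Pathway-style abundance tables are
scaled per sample to copies per million (sum exactly 1e6).

# Paired delta features

The classifier works on per-subject *relative changes*
(`compute_delta`): for feature $f$ and subject $s$,

$$\delta_{sf} = \frac{x^{24w}_{sf} - x^{0w}_{sf}}{\max(|x^{0w}_{sf}|,\ \varepsilon_f)},$$

where $\varepsilon_f$ is the smallest positive value of $f$ observed
anywhere in the cohort. The floor keeps deltas finite and sign-preserving
when a feature is absent at baseline (common for microbial species); a
feature never observed above zero gets $\varepsilon_f = 1$, making its
deltas plain differences. Subjects missing either timepoint are dropped
and reported. Metabolite deltas are computed on the curated
(median-scaled) values.

# The stability-selection classifier

Dimensionality is reduced once, before any resampling: an unsupervised
variance threshold (strictly greater-than) removes near-constant delta
features, then a univariate ANOVA-F selection between the arms keeps the
top fraction of the survivors (ties broken by feature identifier). The
shipped per-modality defaults are variance thresholds 0.01 / 0.25 / 0.027
and selection percentiles 35% / 20% / 1% for microbiome, metabolome and
methylome respectively. The selection percentile is tied to the size of
the feature space: 1% is meaningful against the ~850k-probe EPIC
background, so validation runs on the synthetic cohort (hundreds of
features per modality) scale the methylome percentile to 20% to keep a
comparable number of candidate features; this is configuration, not a
change of procedure.

The classifier itself (`stability_run`) repeats, `n_shuffles` times
(default 100): draw a stratified 80/20 train/test partition; tune a
gradient-boosted tree ensemble on the training part by stratified 3-fold
cross-validated AUC over a small grid (tree depth {2, 3}, learning rate
{0.05, 0.1}); refit the winner with `n_trees` rounds (default 2000); and
score the held-out samples by rank-based AUC (the normalised Mann-Whitney
U of the predicted scores, so it is exactly the probability a random
allogenic subject outranks a random autologous one). Splits are
stratified by arm because at n = 21 unstratified 20% test sets frequently
contain a single class, leaving the AUC undefined; a degenerate draw is
re-drawn from a reserved seed stream and logged. The result aggregates
the per-shuffle AUCs (mean, SD) and the per-feature ensemble gain
importances, which are non-negative and sum to one within each shuffle,
averaged across shuffles. One master seed pins the whole procedure down
bit-for-bit: every shuffle, fold assignment and the ensemble itself (one
thread, fixed internal seed) derive from it.

Reporting conventions: `rank_importance` lists the top-k features (default
20) with the most important feature set to 100% and the rest relative to
it; `rescale_unit_interval` maps summaries affinely onto [0.1, 1] for
spider-plot-style displays.

Smaller `n_shuffles`/`n_trees` values (this vignette's examples and the
validation suite use 25 shuffles and 200 trees) are run-time
configuration; the procedure is unchanged.

## Permutation significance

`permutation_test` re-runs a reduced stability run (default: at most 5
shuffles, no grid search) with the arm labels permuted, and reports

$$p = \frac{1 + \#\{\text{null mean AUC} \ge \text{observed mean AUC}\}}{n_{perm} + 1}.$$

Because the univariate selection uses the labels, each permutation
re-applies the config's full filtering *with the permuted labels*. This
matters: selecting features once on the true labels and only permuting
afterwards makes the null too easy to beat (the selection bias inflates
the observed statistic but not the null), and the test anti-conservative.
With selection inside the loop the test is calibrated: over 20 effect-free
synthetic cohorts at 99 permutations, p < 0.05 occurred in 5% of cohorts.

## Null behaviour at n = 21

On an effect-free cohort the *expected* held-out AUC is 0.5, but the
per-cohort mean AUC is widely dispersed (observed SD ≈ 0.12-0.15 across
master seeds): with a hundred or more features and 21 subjects, some
feature always separates the arms spuriously *in this cohort*, and every
resampled train/test split reuses the same subjects, so the advantage is
consistent across shuffles rather than averaging away. This is intrinsic
to repeated splitting of one small cohort and is precisely why the
permutation test — which regenerates the whole selection-plus-fitting
pipeline under the null — is the calibrated significance statement, while
the raw mean AUC of a single cohort is not. The package's validation
therefore checks the mean AUC aggregated over several master seeds
against the null band, and leaves per-cohort significance to the
permutation test.

# Cross-omics network

`build_network` takes the top 20 ranked features of each modality as
candidate nodes (≤ 60), aligns subjects across modalities by
intersection, computes all pairwise Spearman correlations of the delta
values — within- and cross-modality, both arms pooled — and keeps edges
with $|\rho| \ge 0.6$. Isolated candidates remain as degree-0 nodes.
Edges are not p-value filtered; the t-approximation p is stored as an
edge attribute, as is the signed $\rho$ (colour mapping is left to the
consumer). Export formats are an edge-list TSV and GraphML.

Correlations use deltas (not concatenated before/after values): the
network is meant to show which *changes* travel together across omics
layers, matching the delta-based classifier upstream.

# Baseline statistics

`ttest_from_summary` recomputes two-sample t-tests from printed
(n, mean, SD) summaries, in pooled and Welch (default) variants — at this
study's group sizes both round to the same two decimals for all the
recomputable baseline rows. `mann_whitney` gives the exact two-sided
rank-sum p by full enumeration of the $\binom{n}{n_1}$ rank assignments
for tie-free samples up to n = 12, otherwise a tie- and
continuity-corrected normal approximation. `fisher_exact_rxc` is an exact
Fisher-Freeman-Halton test for any r×c table by recursive enumeration of
all tables with the observed margins (log-factorial arithmetic; the
two-sided p sums probabilities ≤ the observed one with relative tolerance
1e-7 for floating-point ties). At this study's scale (N = 21) full
enumeration costs microseconds; an enumeration budget (default $10^7$
tables) guards against misuse on large tables. `correlate_histology`
screens CpG-by-histology-score pairs (steatosis %, NAS,
necro-inflammation, fibrosis, ballooning) by Spearman correlation, sorted
by $|\rho|$.

P-values are computed and stored at full precision; `make_table1` rounds
to two decimals only in its display column.

# The synthetic cohort generator

`generate_cohort` emulates the study design so that every stage is
testable without patient-level data. All modalities share one latent
Gaussian structure per feature $f$, subject $s$, timepoint $t$:

$$w_{fst} = \mu_f + b_{fs} + e_{fst} \quad (+\ \text{planted terms at } t = 24w),$$

pushed through a modality link: $\exp$ then closure to sum 1 per sample
(microbiome; compositional by construction), $\exp$ (metabolome;
log-normal intensities), logistic (methylome; beta values in [0, 1]).
Metabolite values below their per-metabolite `missing_rate`-quantile are
censored to missing, reproducing detection-floor semantics on the left
tail. Histology scores are ordinal per subject; hepatocyte ballooning is
driven by a latent severity factor that one designated CpG also loads on,
so the histology-correlation stage has a planted positive control.

Key parameter choices (fixed in the generator, stated here as the
package's design):

* **Noise scales.** Between-subject SD 0.5-0.7 and within-subject
  (per-timepoint) SD 0.3 / 0.35 / 0.4 on the log-abundance /
  log-intensity / logit-beta scales — i.e. typical 24-week within-subject
  changes of ~1.3-1.5-fold for abundances and intensities, moderate beta
  shifts for methylation. These are plausible paired-cohort magnitudes
  and keep the relative-change transform's skewness mild enough that a
  standardised latent shift survives as a comparable standardised delta
  shift.
* **Planted effects.** `n_planted_per_modality` features receive an
  allogenic-only shift at week 24 of `effect_size` × SD(latent delta) —
  a Cohen's d on the latent delta scale. The relative-change transform
  attenuates the realised linear-scale d mildly (by ~10-20%).
* **Cross-omics modules.** Each module ties one species, one metabolite
  and one CpG through a shared per-subject factor $z_s$ with loading
  λ = 2.5, *variance-preserving*: a member's own time noise shrinks by
  $\sqrt{1+\lambda^2}$ so its total delta variance matches ordinary
  features, and the pairwise latent correlation is
  $\lambda^2/(1+\lambda^2)$. λ = 2.5 realises a delta Spearman
  $|\rho| \approx 0.8$ at n = 21 after link attenuation — above the 0.6
  network cutoff, but close enough that recovery is a real test. Module
  members take their arm shift *through* the factor ($z_s$ shifted by
  `effect_size`·$\sqrt{1+\lambda^2}/\lambda$ in the allogenic arm), so
  they are simultaneously discriminative (same Cohen's d as direct
  plants) and cross-correlated — as genuinely coupled biology would be.
* **Seed policy.** One master seed; per-modality and per-stage streams
  are derived from it deterministically, so cohorts are bit-reproducible
  and modalities are independent given the seed.

What the generator does *not* emulate: taxon-specific abundance
distributions and zero-inflation patterns of real metagenomes, batch and
array effects, metabolite annotation error, genotype-driven methylation
(beyond the gap-signal caricature used to exercise the filter), or
engraftment dynamics. Passing the validation suite therefore shows the
*pipeline machinery* behaves as specified under a controlled data model;
it does not certify performance on real cohorts.

# Validation scales

The shipped validation suite runs the procedure at reduced but honest
scales chosen for routine execution: synthetic cohorts of 120 species,
200 metabolites and 300 CpGs at the study's n = 21; 25 shuffles and 200
trees per stability run; 99 permutations; 5 master seeds for the null
band, 20 for permutation calibration, 10 for planted-signal recovery at
`effect_size` 1.5 (the operating point used for the planted-recovery
checks; at exactly 1.0, recovering at least 4 of 5 planted features into
the top 20 sits on the edge of what ANOVA-F selection noise at n = 21
allows). Full-scale
settings (100 shuffles, 2000 trees, ≥999 permutations) are pure
configuration via `ml_config`.

# Known limitations

* "Relative change" has no unique definition; the ε-floored form here is
  bounded and sign-preserving but differs from log-ratios, and results
  can differ for features hovering at the detection floor.
* The exact Mann-Whitney enumeration is limited to tie-free samples with
  n ≤ 12; beyond that the corrected normal approximation is used.
* The enumeration test errors beyond its table budget rather than falling
  back to Monte Carlo.
* Importance scores are gain fractions of a boosted ensemble; correlated
  features share credit, so "top 20" membership is a ranking statement,
  not a marginal-effect estimate.
* No multiple-testing correction is applied to baseline comparisons or
  histology screens (by design, matching the reporting conventions the
  package reproduces).
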