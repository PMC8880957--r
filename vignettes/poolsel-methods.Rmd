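---
title: "poolsel: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{poolsel: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolsel)
```

poolsel analyses evolve-and-resequence (E&R) pool-seq experiments: an
ancestral population split into selection regimes, evolved with replication,
and pool-sequenced at several generations. This vignette is the package's own
account of the science it implements: the models, what they assume, the
tunable parameters that matter, what the simulator does and does not emulate,
and the design choices made where the methods literature leaves the design
open. It states no empirical result that the test suite does not itself
compute.

## 1. The data model

The central container, `site_counts`, holds diallelic SNPs (1-based
coordinates) with one (ref, alt) read-count pair per sample. Sample metadata
ties each column to a regime (`ANC` or one of the four selection regimes),
replicate (1–6; 0 for ancestor pools) and generation (0, 13, 22, 31). All
frequencies downstream are read-frequency estimates `p̂ = alt/(ref+alt)`; in
pooled data the read depth, not the number of pooled individuals, is the
realized sample size, and several estimators below correct for both layers.

Filtering mirrors the standard post-variant-calling pipeline, in order:
repeat-mask removal (BED half-open intervals, converted to 1-based on
ingest), removal of sites in the 5% tails of the total-coverage distribution
(nearest-rank/type-1 quantiles; sites with coverage `<=` the lower or `>` the
upper threshold are cut, matching the inequality senses of the convention it
follows), then presence filters. "Present" is not defined in the source
conventions; we define it as per-sample coverage of at least one read, with
`present = "alt"` exposed as an alternative. Every filter logs its drops, and
input sites always reconcile as retained + dropped.

## 2. Ancestral diversity

* Per-site minor allele frequency: `min(p̂, 1 − p̂)`.
* Coverage-weighted heterozygosity: `π = C/(C−1) · 2 p̂ (1 − p̂)` with `C` the
  read depth. The `C/(C−1)` factor is the finite-sample correction for
  resampling the same chromosome from the pool; the genome-wide summary is the
  unweighted mean over SNPs. Exactly which finite-sample correction the
  classic pooled estimator intends is a known ambiguity; this reading is
  validated by its `2p(1−p)` large-coverage limit (tested to 1e-5 at C = 1e6).
* Windowed Watterson θ: per 1 kb tile, `θ̂_w = S / (a(n_eff) · L)` with
  `a(n) = Σ_{i=1}^{n−1} 1/i` and `n_eff` the rounded mean coverage of the
  window's SNPs. Tiling (not sliding) windows are the default because
  genome-wide means over overlapping windows double-count S; a `stride`
  argument provides sliding windows for visualisation. The choice of `n` for
  `a(n)` is likewise unstated in the conventions we follow; per-window mean
  coverage is the default because coverage is the realized sample size.
* Arm/center comparisons use a two-sample Kolmogorov–Smirnov test (asymptotic
  p-values) on any per-site or per-window statistic, and per-chromosome
  comparisons use Welch's t on per-window θ̂_w.

## 3. Temporal Ne

For frequencies `x` (generation 0) and `y` (generation t), the standardized
variance is `F_c = (x − y)² / ((x + y)/2 − x·y)`; loci fixed for the same
allele at both ends are inadmissible and excluded. The multi-locus `F̄_c`
pools numerators and denominators across loci (a ratio of sums — equivalently
a heterozygosity-weighted mean of per-locus F_c). This choice matters: with a
rare-allele-skewed spectrum the unweighted mean of per-locus F_c is strongly
biased (loci that drift to loss leave the admissible set, and the ratio is
noisiest exactly where weights should be smallest). In the package's own
recovery experiment (acceptance suite) the weighted form recovers a true Ne
of 500 within a few percent while the unweighted mean misses by ~50%; the
unweighted form is retained as `aggregate = "mean"` for comparison only.

The estimator is `N̂e = t / (2(F̄_c − c₀ − c_t))` with per-stage sampling
corrections:

* `waples_planII`: `c = 1/(2S)` with `S` the read depth — reads standing in
  for the sampled individuals, ignoring the pooling layer;
* `jonas_planII`: the two-stage pool-seq correction
  `c = 1/R + (1 − 1/R)/(2·N_pool)`, the exact variance fraction of sampling
  `2·N_pool` chromosomes and then `R` reads.

A corrected `F̄_c ≤ 0` means the drift signal is below sampling noise and is
reported as `Ne = +Inf` with a flag. Under-correcting (the read-only form)
leaves sampling noise inside `F̄_c` and biases Ne downward; the test suite
asserts the two-stage form is the more accurate of the pair on simulated
pool-seq drift, which is its reason to exist.

Defaults for the experiment-level wrapper `ne_table()`: the three ancestor
pools are merged by summing counts (generation 0) and paired with each
replicate's final-generation sample (`t = 31`); the "common set" of SNPs for
a pair is those covered in both samples. Per-replicate genome-wide Ne feeds a
fixed-effects one-way ANOVA across regimes and a Welch t between autosomes
and X. The breeding-male bound solves `Ne = 4·N_m·N_f/(N_m + N_f)` for `N_m`
assuming all `N_f = 2,500` females reproduced; it is monotone in Ne on
`(0, 4N_f)` with a pole at `4N_f`.

## 4. Allele-frequency-change scans

Both scans are fixed-effects grouped binomial-logit GLMs — the formulas of
the convention they follow are plain `glm` formulas, so no random effects are
fit, and replicate samples enter as independent binomial observations.

* **Model 1** (`model1_contrasts`): a five-level factor (ancestor + four
  regimes) fit per SNP on final-generation samples, which is saturated and
  therefore solved in closed form (cell MLEs); the reported statistics are
  Wald contrasts `logit p̂_ANC − logit p̂_regime` with
  `SE = sqrt(Σ 1/cell)`. When a contrast's 2×2 table has a zero cell, 0.5 is
  added to all four cells (Haldane–Anscombe) and the row is flagged
  `adjusted` — this keeps completed sweeps in the result with finite
  statistics rather than discarding the strongest signals. Bonferroni `m` is
  the number of SNPs; the four contrasts of a SNP share the threshold (the
  convention is silent; both behaviours are obtainable by rescaling `alpha`).
* **Model 2** (`model2_scan`): per SNP and regime, alternate counts on
  numeric generation (0, 13, 22, 31) over the ancestor pools plus the
  regime's 18 samples, fit by iteratively reweighted least squares. The
  reported statistic is the two-sided Wald z of the generation slope
  (log-odds per generation), Bonferroni-corrected over the SNPs fit in that
  regime. SNPs with fewer than three informative generations, or monomorphic
  across all observations, are skipped and counted. The production path is a
  vectorised two-parameter IRLS identical in math to the general
  `irls_binomial_fit` (score tolerance 1e-8, 50-iteration cap, step-halving
  so the deviance never increases, covariance = inverse Fisher information);
  the general fitter is tested against the closed-form saturated solutions
  and an independent reference GLM implementation.

Two calibration facts are asserted by the suite and worth knowing. First,
with drift suppressed, Wald p-values are uniform where the normal
approximation holds but visibly discrete and *conservative* at sparse SNPs
(few alternate reads overall); family-wise error at the Bonferroni cut stays
controlled. Second — the documented anti-property — with realistic drift
(Ne ≈ 500) the scan's neutral-site rejection rate is far above nominal: the
binomial GLM treats drift as signal, because replicate-shared sampling
variance is the only noise it models. Model 2's replication across six
replicates dampens but does not remove this; significant SNPs in a
small-population E&R design are "drifted or selected", and the peak-calling
layer (clustering, cross-regime overlap) is the practical defence.

## 5. Significance peaks

A peak is any maximal cluster of significant SNPs in which at least
`min_snps` (3, or 5 for the conservative call) fall within a 1 kb span. The
span criterion slides with the SNPs rather than using fixed tiles: fixed
tiles split clusters at arbitrary phase boundaries, and reported peak widths
(the span of member SNPs, `end − start + 1`) only make sense for
SNP-anchored clusters. A tiling mode is retained for sensitivity analysis.
The caller is verified against a brute-force enumeration oracle on random
position sets; one consequence of the stated rule worth noting is that two
dense runs joined by any qualifying bridge subset chain into a single peak.

Peaks wholly inside the same gene are merged (counts summed); peaks partially
overlapping a gene are not merged into it. Classification is overlap-based:
`genic` (coding gene), `pseudogenic`, `mixed` (both), `intergenic` (neither),
with `gene_id` the largest-overlap gene. Cross-regime identity is ≥1 bp
interval overlap, chained transitively, reported as combination counts.
Arm/center enrichment is a 1-df goodness-of-fit χ² of peak midpoints against
the ancestral SNP arm/center fractions — the right null, since peaks inherit
the arm-biased SNP density even without selection.

## 6. The simulator (the stated world)

`sim_config()` defaults encode the experimental design the package targets:

| parameter | default | meaning |
|---|---|---|
| `census` | 5,000 | diploid census per replicate |
| `true_ne` | 500 | drift Ne (~10% of census, the scale such experiments estimate) |
| regimes × replicates | 4 × 6 | selection regimes, replicates |
| `sampled_generations` | 0, 13, 22, 31 | sequenced time points |
| `n_ancestor_pools` | 3 | independent ancestor pool extractions |
| `pool_individuals` | 2,500 | diploids per sequencing pool |
| `coverage_mean` | 162/24/26/50× | mean depth at G0/13/22/31 |
| `arm_density_ratio` | 5:3 | arm:center SNP density |
| `maf_alpha`, `maf_beta` | 0.26, 3.5 | MAF ~ 0.5·Beta(α, β) |

The MAF shape was chosen once so that the mean expected heterozygosity
`2p(1−p)` is ≈ 0.06 — the ancestral genome-wide mean π scale of the
experiments emulated — with the strong rare-allele skew such populations
show; the default toy genome is six 1 Mb chromosomes (25/50/25% arm/center
domains) rather than full-length chromosomes, since all statistics are
per-site or per-window. Trajectories are a single unbroken Wright–Fisher
lineage per regime × replicate: a deterministic multiplicative
(haploid-equivalent) selection update `p' = p(1+s)/(1+ps)` followed by
binomial resampling of `2·Ne` allele copies. No fitness model is prescribed
by the conventions we follow; the multiplicative update was chosen for
analytic tractability (its one-step closed form is an oracle in the tests).
Pool-seq counts are two-stage binomial: pool frequency
`q ~ Bin(2·N_pool, p)/(2·N_pool)`, then `alt ~ Bin(depth, q)` with per-site
Poisson depths. Fertility assays are beta-binomial around per-population
siring probabilities; ancestral defaults (44.5% total, 4.1% post-insemination
success) are the printed means of the emulated assays, evolved defaults are
fold changes on them (post: 5.0/4.5/5.5/6.8 for WS-P&P/WS-PO/BS-P&P/BS-PO),
with ~342 progeny per assay so three pooled ancestral assays total ~1,026.
Effect sizes for selected loci have no empirical anchor; they are
conventions, not inferences about any real experiment.

Determinism is a contract: a master seed is hierarchically split
(`derive_seed`) per component — ancestral pool, each trajectory, each
sample's sequencing — so any subset regenerates identically and a fixed seed
fixes every emitted byte.

What the simulator deliberately does **not** emulate: linkage (sites drift
independently — so peak clustering of *causal* hits, LD shadows and
hitchhiking are absent), individual-based mating or sperm-storage mechanics,
the alternation of selection and recovery generations (collapsed into
effective per-generation drift, since the analysis only consumes
sampled-generation frequencies), read-level artefacts (mapping error, base
quality, reference bias) and real repeat structure. A green test therefore
establishes that the statistics do what they claim under drift + two-stage
sampling noise; it does not establish robustness to LD or mapping artefacts.

## 7. Fertility statistics

The one-sample proportion test follows the R-ecosystem convention exactly
(Yates continuity capped at `|x − n·p₀|`, 1-df χ² tail, continuity-corrected
Wilson score interval) and is tested against that implementation across a
grid; the continuity correction is needed to reproduce the χ² magnitudes the
emulated analyses print. The pooled ancestral test sums counts across the
three assays (pooling, not averaging, is what single reported χ² values
imply). Fold changes aggregate assay → replicate mean → regime mean, and the
post-insemination contribution fraction is `100 · post/total` of the
ancestral mean proportions.

The planned contrasts use a quasi-binomial fixed-effects GLM on the regime
factor, with replicate-level extra-binomial variance absorbed by the
estimated dispersion. The mixed-model (random-effects) formulation the
emulated analyses mention is deliberately not reproduced: its random-effects
structure is unstated, and the deliverables — the two contrast families
(each regime vs ancestor; each directed-selection regime vs the baseline
regime) — are available from the dispersion-scaled fixed-effects fit. Exact
mixed-model z-values will differ; treat these as approximate.

## 8. Numerical choices and degenerate inputs

* IRLS: score convergence at 1e-8, 50 iterations, deviance-monotone
  step-halving, |coefficient| > 30 treated as separation (fit flagged, p set
  to NA, never "significant").
* Coverage-tail filter on an all-equal coverage distribution would remove
  everything under the `<=` rule; it warns and removes nothing.
* `theta_w` windows with S > 0 but `n_eff < 2` are flagged undefined (NA).
* `fc_per_locus` denominators ≤ 0 exclude the locus; an empty admissible set
  errors; a corrected F̄_c ≤ 0 yields `+Inf` Ne with a flag.
* Welch t with both groups constant and equal means is reported NA.
* χ² enrichment warns when an expected cell drops below 1.
* Bonferroni thresholds are exact `α/m`; all tests are two-sided.

## 9. Known limitations

* Drift-vs-selection confounding in the GLM scans (section 4) is inherent to
  the method, not a bug; interpret per-SNP significance jointly with Ne.
* The Ne estimators assume unlinked neutral loci; background selection and
  sweeps bias them downward.
* Presence filters operate on coverage, so "present" is a sequencing
  property, not a biological one.
* The fertility contrasts are quasi-binomial approximations to a mixed
  model (section 7).
* Peak calling knows nothing about LD; peak width reflects significant-SNP
  span only.
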