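---
title: "Methods: transcriptomic aging clocks and time-course analysis for dauer diapause"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptomic aging clocks and time-course analysis for dauer diapause}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dauerclock)
```

# Scope

`dauerclock` provides the statistical machinery used to study transcriptomic
aging in *C. elegans* dauer diapause and dauer exit: a binarized-expression
biological age clock, a stochastic-data based clock score, per-gene linear
trend differential expression with trajectory clustering, hypergeometric
over-representation analysis, and the gene-length-dependent transcription
decline (GLTD) statistic. Because the original count data live in external
repositories, the package ships a negative-binomial simulator whose output has
the statistical structure every downstream stage assumes; all tests and the
acceptance script run end-to-end on simulated data.

# The binarized clock

## Binarization

Expression values are converted per sample into binary states: the threshold
is the median of the sample's *nonzero* gene values, and a gene is set to 1
iff its value is strictly above the threshold. Two deliberate readings are
fixed here for reproducibility:

* "above the median" is taken strictly — genes exactly at the threshold are 0.
  With an even number of nonzero genes the interpolated median leaves exactly
  half of them above; with an odd number, strictly under half.
* zero-count genes are excluded from the median computation but still
  binarized, and therefore are always 0. Whether a published clock instead
  compares zeros against the median is ambiguous; our choice is documented
  behaviour, not a claim about any external implementation.

Binarization trades expression magnitude for robustness: cross-platform and
cross-study level shifts that defeat magnitude-based clocks largely cancel
when only the within-sample rank relative to the median is kept.

## Biological age labels and training

Training labels are *biological* ages: chronological age rescaled by the
ratio of a reference lifespan to the cohort's median lifespan
(`rescale_biological_age()`). A cohort that lives twice as long as the
reference is biologically half as old at the same chronological age. The
reference defaults to the mean of the training cohorts' median lifespans; the
choice of reference only sets the scale of the output hours and cancels in
the aging-rate statistic.

`train_clock()` fits an elastic net (glmnet) of biological age on the
binarized states. Defaults: mixing parameter `alpha = 0.5` (ridge/lasso
compromise — correlated informative genes should share weight, yet the model
should stay sparse), penalty chosen by 5-fold cross-validation minimizing
MSE at `lambda.min`, features not standardized (all predictors are already
on the common 0/1 scale, and standardizing would inflate the weight of
rarely-on genes). The CV fold assignment derives from the recorded seed, so
training is reproducible. Only genes with nonzero coefficients are kept.

Prediction (`predict_age()`) is the sum of the coefficients of the clock
genes in state 1, plus the intercept. Clock genes absent from a query matrix
count as state 0 with a warning, so a model transfers across annotation
versions; the cost is a downward bias when many positive-coefficient genes
are missing, which the warning makes visible.

## The aging rate

`aging_rate()` is the change in predicted biological age divided by the
elapsed chronological time, dimensionless. Rates below 1 mean the
transcriptome ages more slowly than chronological time — the headline
phenomenon in dauer, where the rate drops from about 0.79 over days 1–4 to
about 0.12 over days 4–30 of arrest.

# The stochastic clock score

Samples are log10-transformed after a single pseudo-count, min-max normalized
to [0, 1] per sample, binarized with the same strict-median rule (on the
normalized scale, with zero-count genes always 0), and the binarized states
of the clock genes are summed. The score counts how many clock genes have
switched on, tracking the accumulation of stochastic transcriptional
activation with age.

Whether the published score sums the *binarized* states or the *min-max
normalized* values is genuinely ambiguous in its one-sentence description;
we implement the binarized sum as the default and expose
`sum_mode = "normalized"` as a sensitivity analysis. Neither mode is asserted
to be the original computation.

`select_clock_genes()` is this package's own concretization of clock-gene
selection (the original procedure lives in prior work): candidates must have
consensus state 0 in the youngest age group, are ranked by the OLS slope of
their mean binarized state against age, and ties break lexicographically by
gene id so selection is deterministic.

# Trend differential expression

Counts are prefiltered (≥ 10 counts in ≥ 3 samples, the smallest group
size), normalized with median-of-ratios size factors (computed over genes
expressed in every sample, rescaled to geometric mean 1 for
identifiability), and log2-transformed with a pseudocount of 0.5 — the
standard log-CPM-style offset, configurable.

The per-gene test is ordinary least squares of the log2 values on the
continuous time covariate (dauer day or exit hour), so the slope is the
log2 fold change per unit time; significance is the slope t-test with
Benjamini–Hochberg adjustment at α = 0.05. This Gaussian OLS model is a
deliberate divergence from negative-binomial GLM likelihood-ratio machinery:
it is self-contained, has a closed-form oracle the tests verify to 1e-9, and
behaves well on the simulator's data. Gene-level results on real data are
not expected to match an NB GLM gene-for-gene, particularly for low counts
where the Gaussian approximation on the log scale is weakest. Note the
pseudocount slightly compresses slopes (a noiseless doubling per day yields
a fitted slope of ~0.998, not 1.000, at typical count magnitudes).

A two-group variant (`de_two_group()`, OLS on a 0/1 indicator ≡ pooled
t-test) provides the UV-treated versus untreated contrast feeding the GLTD
test.

## Trajectory clustering

Per-gene profiles (replicate means per timepoint, z-scaled per gene) are
k-means clustered with `nstart = 100` restarts and `iter.max = 1000`,
matching the clustering settings of the motivating analysis. The "elbow" is
made explicit: the interior k maximizing the second difference of the WCSS
curve. On fixtures dominated by two anti-correlated monotone archetypes the
second difference peaks at k = 2 even when four planted shapes exist — the
elbow is reported, but cluster membership at any scanned k remains available
in `assignments_by_k`, and the recovery tests assert agreement with planted
labels at the planted k. Genes with zero variance across timepoints have no
z-scored profile and are excluded with a warning.

# Over-representation analysis

`ora()` is the classical one-sided hypergeometric test: with universe size
N, set size m (within the universe), query size n and overlap k, p =
P(X ≥ k) for X hypergeometric(N, m, n), BH-adjusted across sets. The
universe is the set of genes passing the prefilter — a practical proxy for
"all genes the DE analysis could have called", replacing tool-internal
independent filtering. Gene ratio (k/n) and rich factor (k/m) are reported
for bubble-plot style summaries. Under-representation and ranked (GSEA-style)
tests are out of scope; gene sets come from user-supplied GMT files rather
than live database queries, keeping the package fully offline.

# GLTD

`gltd_test()` compares the gene-length distributions of up- and
down-regulated sets with a two-sided Mann–Whitney U test: midrank tie
handling, exact null distribution when there are no ties and
n_up·n_down ≤ 10,000, otherwise the normal approximation with tie
correction (no continuity correction, matching the plain large-sample
formula). Two-sided p is twice the smaller tail, capped at 1; the effect
direction is reported separately from the median comparison, since the
sidedness of the original analysis is not stated. The GLTD signature —
down-regulated genes systematically longer — follows from
transcription-blocking lesions accumulating with gene length.

# The simulator

`simulate_timecourse()` draws negative-binomial counts (gamma–Poisson,
shared dispersion; var = μ + φμ², the standard bulk RNA-seq noise model)
with log-normal library sizes and five gene programs on a flat background:

* **age-up / age-down**: mean changes by ± effect·(age in days) in log2
  units. Default effect 0.2 log2/day — ~64-fold cumulative over the 30-day
  default course, the scale of strongly age-regulated genes; short planted
  fixtures (a few days) use 1.0 log2/day.
* **transient**: a Gaussian bump centred mid-course (σ = span/4) peaking at
  effect·span/2 log2 units.
* **oscillatory**: sinusoid with 8 h period (mimicking developmental
  expression oscillations), amplitude 1 log2 unit by default.
* **drift**: genes start at a low baseline (10% of a typical baseline) and
  switch to a high state (+4 log2) per sample with hazard
  1 − exp(−0.05·days) — the binarized-state flips the stochastic clock is
  built to count.

Expected counts are renormalized per sample so the library size is
interpretable; the resulting compositional coupling between programs is
intentional (it is exactly what median-of-ratios normalization corrects when
most genes are flat) — configurations in which effect genes dominate the
library are pathological by construction, which motivates the moderate
default effect size. Gene lengths are log-uniform over 200 bp–100 kb,
spanning the dynamic range GLTD needs. Defaults: 2,000 genes, 3 replicates
at 24/96/360/720 h (dauer days 1/4/15/30).

`simulate_lifespan_cohorts()` reuses the same machinery with expression
driven by biological age, so cohorts with different drawn lifespans provide
lifespan-invariant training signal; `apply_uv_effect()` multiplies each
gene's expected count by exp(−lesion_rate·dose·length_kb) and redraws
counts from the stored generating means.

What the simulator does **not** emulate: batch effects, GC/length biases in
counting, gene–gene correlation beyond library composition, isoform
structure, or the biology linking programs (a gene is exactly one program).
Passing recovery tests therefore demonstrates the estimators' correctness
under their stated model, not performance on real library-prep artefacts.

# Problem sizes and fixed seeds

Test and acceptance fixtures are sized for quick, well-powered checks:
500-gene planted-trend fixtures (10% up, 10% down, 4 timepoints × 3
replicates), a 500-gene 60-sample cohort design (4 cohorts × 5 timepoints ×
3 replicates, effect 0.3 log2/day) for clock recovery, 200-gene archetype
fixtures for clustering, and the 2,000-gene default course for the UV/GLTD
power check. Brute-force oracles (draw enumeration for the hypergeometric
tail, labeling enumeration for Mann–Whitney) run at universe/pool sizes ≤ 12
where complete enumeration is cheap. All fixture seeds are fixed in the test
code; generator parameters were chosen once, as above, as realistic
emulations of the study design.

# Known limitations

* The Gaussian trend test will be anticonservative for very low counts; the
  prefilter is load-bearing.
* The elastic-net clock predicts a step function of the selected genes'
  states; with few informative genes the prediction is coarsely quantized.
* The elbow rule is a heuristic; inspect the WCSS table rather than trusting
  the selected k blindly.
* Published clock coefficient sets are not bundled; `read_clock_model()`
  accepts an external coefficient table in the documented JSON schema.
* The pipeline's command-line wrapper is a thin convenience; the R functions
  are the interface of record.
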