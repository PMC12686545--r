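# dauerclock

Transcriptomic aging analysis for *C. elegans* dauer diapause RNA-seq time
courses.

Dauer is an alternative, stress-resistant larval stage in which development
arrests, sometimes for weeks, without the phenotypic decline of normal
aging. Bulk RNA-seq time courses of dauer arrest and dauer exit raise a set
of recurring analysis problems: estimating each sample's *biological* age
from its transcriptome, quantifying how fast biological age advances during
arrest, finding genes with monotone or transient expression trajectories,
grouping trajectories into interpretable programs, testing pathway
over-representation, and detecting DNA-damage-driven transcription stress
from the lengths of affected genes. `dauerclock` implements this toolkit for
computational biologists working with such time courses, and ships a
ground-truth count simulator so every estimator is testable end to end
without external data.

## Methods at a glance

* **Binarized aging clock** — per sample, a gene's state is 1 iff its
  expression is strictly above the median of the sample's nonzero values
  (zero-count genes are always 0). A clock is an elastic-net regression of
  biological age on these states; biological age labels come from rescaling
  chronological age by the ratio of a reference lifespan to the cohort's
  median lifespan, *t*<sub>bio</sub> = *t*<sub>chrono</sub> ·
  *L*<sub>ref</sub>/*L*<sub>cohort</sub>. The predicted biological age (PBA)
  of a sample is Σ<sub>g: state 1</sub> β<sub>g</sub> + β<sub>0</sub>, and
  the **aging rate** between two timepoints is ΔPBA/Δ*t*<sub>chrono</sub>.
* **Stochastic clock score** — log10(x+1), per-sample min–max to [0, 1],
  the same strict-median binarization, then the sum of states over a clock
  gene set: a count of stochastically switched-on genes that rises with age.
* **Trend differential expression** — median-of-ratios size factors, then
  per-gene OLS of log2(normalized + 0.5) on the continuous time covariate;
  the slope is the log2 fold change per dauer day (or exit hour), tested
  with a slope t-test and BH adjustment. Trajectories (replicate means,
  z-scaled) are k-means clustered (nstart = 100, iter.max = 1000) with an
  explicit elbow rule on the WCSS curve.
* **Over-representation analysis** — one-sided hypergeometric tail
  P(X ≥ k) for each GMT gene set against the prefiltered-gene universe,
  BH-adjusted, with gene-ratio (k/n) and rich-factor (k/m) statistics.
* **GLTD** — gene-length-dependent transcription decline: a two-sided
  Mann–Whitney U test (exact when feasible, midrank ties otherwise)
  comparing the length distributions of up- versus down-regulated genes;
  transcription-blocking lesions hit long genes more, so a longer down-set
  is the damage signature.
* **Simulator** — negative-binomial counts with log-normal library sizes
  and planted age-monotone, transient, oscillatory and drift programs;
  lifespan-labeled cohorts for clock training; UV effects that multiply
  expected counts by exp(−rate·dose·length<sub>kb</sub>).

See `vignettes/dauerclock-methods.Rmd` for assumptions, parameter defaults
and design decisions.

## Worked example

```r
library(dauerclock)

# Aging rate from predicted biological ages: PBA 123 h at dauer day 1
# (24 h chronological) and 180 h at day 4 (96 h)
aging_rate(123, 180, 24, 96)
#> [1] 0.7916667            # the transcriptome aged 57 h in 72 h: rate ~0.79
round(aging_rate(180, 256, 96, 720), 2)
#> [1] 0.12                 # ...and nearly stalls between day 4 and day 30

# Train a clock on simulated lifespan-labeled cohorts, hold one cohort out
coh <- simulate_lifespan_cohorts(
  sim_config(n_genes = 500, seed = 6, timepoints_h = c(24, 96, 240, 480, 720),
             frac_age_up = 0.1, frac_age_down = 0.1,
             effect_size_log2_per_day = 0.3),
  n_cohorts = 4, lifespan_range_h = c(400, 1200))
bin  <- binarize(coh$counts)
hold <- coh$metadata$group == "cohort4"
model <- train_clock(bin[, !hold], coh$truth$samples$true_bioage_h[!hold], seed = 1)
model
#> Binarized aging clock: 62 genes, intercept 708.89 h
pba <- predict_age(bin[, hold], model)
cor(pba$predicted_biological_age_h, coh$truth$samples$true_bioage_h[hold])
#> [1] 0.949                # held-out biological age is recovered

# GLTD on a UV-treated redraw of a simulated course
sim <- simulate_timecourse(sim_config(n_genes = 2000, seed = 21))
uv  <- apply_uv_effect(sim$counts, sim$truth, dose = 1,
                       lesion_rate_per_kb_per_dose = 0.1, seed = 22)
both <- cbind(sim$counts, uv)
colnames(both) <- c(paste0(colnames(sim$counts), "_ctl"),
                    paste0(colnames(sim$counts), "_uv"))
de   <- de_two_group(normalize_counts(prefilter(both))$normalized,
                     rep(c("ctl", "uv"), each = ncol(sim$counts)))
lens <- setNames(sim$truth$genes$length_bp, sim$truth$genes$gene_id)
gltd_test(de$gene_id[de$direction == "up"],
          de$gene_id[de$direction == "down"], lens)
#> GLTD: n_up=558 (median 762 bp), n_down=794 (median 31575 bp)
#> U=4.0, approx. p=1.24e-215, down-set longer
```

The whole pipeline (simulate → normalize → clocks → trend → cluster →
overlap → enrichment → GLTD, with a hash-stable run manifest) runs with
`run_pipeline(list(seed = 1, outdir = "out"))`, or from a shell via
`Rscript inst/scripts/dauerclock.R run-all --config config.yaml`.

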