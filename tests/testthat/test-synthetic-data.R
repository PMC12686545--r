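test_that("simulator is deterministic under a fixed seed", {
  cfg <- sim_config(n_genes = 100, seed = 42)
  a <- simulate_timecourse(cfg)
  b <- simulate_timecourse(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth$genes, b$truth$genes)
})

test_that("config validation rejects invalid designs", {
  expect_error(sim_config(timepoints_h = c(24, 24, 96)), "strictly increasing")
  expect_error(sim_config(nb_dispersion = 0), "dispersion")
  expect_error(sim_config(frac_age_up = 0.7, frac_age_down = 0.6), "fractions")
  expect_error(sim_config(uv_dose = -1), "uv_dose")
})

test_that("null config gives flat genes with slopes centered on zero", {
  cfg <- sim_config(n_genes = 300, seed = 3,
                    frac_age_up = 0, frac_age_down = 0, frac_transient = 0,
                    frac_oscillatory = 0, frac_drift = 0)
  sim <- simulate_timecourse(cfg)
  expect_true(all(sim$truth$genes$program == "flat"))
  nn <- normalize_counts(prefilter(sim$counts))
  tt <- trend_test(nn$normalized, sim$metadata$timepoint_h / 24)
  expect_lt(abs(mean(tt$slope)), 0.01)
  # empirical false-positive rate of the downstream test at most 2x nominal
  expect_lte(mean(tt$p <= 0.05), 0.10)
})

test_that("simulated counts follow the negative-binomial mean-variance law", {
  # constant library sizes so each flat gene has a constant mean across
  # replicates; compare pooled variance against mu + disp * mu^2
  cfg <- sim_config(n_genes = 400, n_samples_per_timepoint = 30, seed = 8,
                    timepoints_h = c(24, 48), library_size_cv = 0,
                    frac_age_up = 0, frac_age_down = 0, frac_transient = 0,
                    frac_oscillatory = 0, frac_drift = 0, nb_dispersion = 0.1)
  sim <- simulate_timecourse(cfg)
  x <- sim$counts[, sim$metadata$timepoint_h == 24]
  mu <- rowMeans(x)
  v <- apply(x, 1, var)
  keep <- mu > 50
  ratio <- sum(v[keep]) / sum((mu + 0.1 * mu^2)[keep])
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.2)
})

test_that("lifespan cohorts rescale biological age by median lifespan", {
  coh <- sim_clock_cohorts(seed = 2)
  md <- coh$metadata
  ref <- coh$truth$reference_lifespan_h
  expect_equal(coh$truth$samples$true_bioage_h,
               md$timepoint_h * ref / md$median_lifespan_h)
  expect_equal(ref, mean(unique(md$median_lifespan_h)))
  # replicates share the generating composition: mu depends on sample only
  # through biological age and library size
  mu <- attr(coh$counts, "mu")
  q <- sweep(mu, 2, colSums(mu), "/")
  reps <- which(md$group == md$group[1] & md$timepoint_h == md$timepoint_h[1])
  expect_equal(q[, reps[1]], q[, reps[2]], tolerance = 1e-12)
  expect_error(
    simulate_lifespan_cohorts(sim_config(n_genes = 10),
                              lifespan_range_h = c(0, 500)),
    "lower bound"
  )
  expect_error(
    simulate_lifespan_cohorts(sim_config(n_genes = 10), n_cohorts = 1),
    "n_cohorts"
  )
})

test_that("UV retention follows the lesion model and is length-monotone", {
  # all genes 10 kb: retention exactly exp(-rate * dose * 10)
  cfg <- sim_config(n_genes = 50, seed = 6,
                    gene_length_range_bp = c(10000, 10000))
  sim <- simulate_timecourse(cfg)
  uv <- apply_uv_effect(sim$counts, sim$truth, dose = 1,
                        lesion_rate_per_kb_per_dose = 0.1, seed = 1)
  expect_equal(unname(attr(uv, "retention")), rep(exp(-1), 50))
  # dose 0: retention 1 everywhere
  uv0 <- apply_uv_effect(sim$counts, sim$truth, dose = 0,
                         lesion_rate_per_kb_per_dose = 0.1, seed = 1)
  expect_equal(unname(attr(uv0, "retention")), rep(1, 50))
  # mixed lengths: retention non-increasing in length and in dose
  cfg2 <- sim_config(n_genes = 200, seed = 6)
  sim2 <- simulate_timecourse(cfg2)
  r1 <- attr(apply_uv_effect(sim2$counts, sim2$truth, 1, 0.1, seed = 1),
             "retention")
  r2 <- attr(apply_uv_effect(sim2$counts, sim2$truth, 2, 0.1, seed = 1),
             "retention")
  len <- sim2$truth$genes$length_bp
  ord <- order(len)
  expect_true(all(diff(r1[ord]) <= 0))
  expect_true(all(r2 <= r1))
  expect_error(apply_uv_effect(sim2$counts, sim2$truth, -1, 0.1), "dose")
})

test_that("fixtures round-trip through the directory format", {
  sim <- simulate_timecourse(sim_config(n_genes = 40, seed = 12))
  gs <- build_program_genesets(sim$truth, n_random = 3, seed = 1)
  dir <- withr::local_tempdir()
  write_fixture(dir, sim$counts, sim$metadata, sim$truth, gs)
  back <- read_fixture(dir)
  plain <- sim$counts
  attributes(plain) <- attributes(plain)[c("dim", "dimnames")]
  expect_identical(back$counts, plain)
  expect_equal(back$metadata, sim$metadata)
  expect_equal(back$truth$genes, sim$truth$genes)
  expect_equal(back$truth$samples, sim$truth$samples)
  expect_identical(back$genesets$sets, gs$sets)
  # missing metadata file is named in the error
  file.remove(file.path(dir, "metadata.tsv"))
  expect_error(read_fixture(dir), "metadata")
})
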