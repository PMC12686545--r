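test_that("prefilter keeps genes with >= 10 counts in >= 3 samples", {
  m <- rbind(
    pass_exact = c(10, 10, 10, 0, 0, 0),
    fail_nine = c(9, 9, 9, 9, 9, 9),
    pass_high = c(100, 200, 300, 400, 0, 0),
    fail_two = c(50, 50, 0, 0, 0, 0),
    pass_all = c(11, 12, 13, 14, 15, 16)
  )
  colnames(m) <- paste0("s", 1:6)
  out <- prefilter(m)
  expect_setequal(rownames(out), c("pass_exact", "pass_high", "pass_all"))
  expect_warning(prefilter(m, min_count = 1000), "every gene")
})

test_that("median-of-ratios size factors satisfy their closed forms", {
  a <- c(100, 50, 200, 10)
  m <- cbind(s1 = a, s2 = a)
  rownames(m) <- paste0("g", 1:4)
  nf <- normalize_counts(m)
  expect_equal(unname(nf$size_factors), c(1, 1))
  # doubling a sample doubles its factor; factors keep geometric mean 1
  m2 <- cbind(s1 = a, s2 = 2 * a)
  rownames(m2) <- paste0("g", 1:4)
  nf2 <- normalize_counts(m2)
  expect_equal(unname(nf2$size_factors[2] / nf2$size_factors[1]), 2)
  expect_equal(exp(mean(log(nf2$size_factors))), 1)
  # no gene expressed everywhere -> undefined
  bad <- cbind(s1 = c(5, 0), s2 = c(0, 5))
  rownames(bad) <- c("g1", "g2")
  expect_error(normalize_counts(bad), "size factors")
})

test_that("trend slopes equal the closed-form OLS oracle", {
  set.seed(21)
  n_genes <- 40
  times <- rep(c(0, 1, 3, 7, 10), each = 2)
  m <- matrix(rgamma(n_genes * length(times), 5, 0.05), n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_along(times))))
  tt <- trend_test(m, times)
  for (i in seq_len(n_genes)) {
    fit <- summary(lm(log2(m[i, ] + 0.5) ~ times))
    expect_equal(tt$slope[i], unname(coef(fit)[2, 1]), tolerance = 1e-9)
    expect_equal(tt$se[i], unname(coef(fit)[2, 2]), tolerance = 1e-9)
    expect_equal(tt$p[i], unname(coef(fit)[2, 4]), tolerance = 1e-9)
  }
  # BH step-up: q is monotone in p and bounded by 1
  ord <- order(tt$p)
  expect_true(all(diff(tt$q[ord]) >= -1e-12))
  expect_true(all(tt$q <= 1))
  expect_true(all(tt$q >= tt$p))
})

test_that("a noiseless doubling gene has slope ~1 log2/day and a flat gene is ns", {
  m <- rbind(doubling = c(100, 200, 400, 800),
             flat = c(300, 300, 300, 300))
  colnames(m) <- paste0("d", 0:3)
  tt <- trend_test(m, 0:3)
  # pseudocount 0.5 shifts the slope slightly below 1; exact value from the
  # closed form on log2(x + 0.5)
  expect_equal(tt$slope[1], 1, tolerance = 0.005)
  y <- log2(c(100, 200, 400, 800) + 0.5)
  expect_equal(tt$slope[1], unname(cov(y, 0:3) / var(0:3)), tolerance = 1e-12)
  expect_equal(tt$slope[2], 0)
  expect_equal(tt$direction[2], "ns")
  expect_error(trend_test(m, c(1, 1, 2, 2)), "distinct")
})

test_that("planted monotone effects are recovered with controlled FDR", {
  sim <- sim_trend_recovery(seed = 11)
  nn <- normalize_counts(prefilter(sim$counts))
  tt <- trend_test(nn$normalized, sim$metadata$timepoint_h / 24)
  tr <- merge(tt, sim$truth$genes, by = "gene_id")
  sens_up <- mean(tr$direction[tr$program == "up"] == "up")
  sens_down <- mean(tr$direction[tr$program == "down"] == "down")
  called <- tr$direction != "ns"
  fdr <- mean(tr$program[called] == "flat")
  expect_gte(sens_up, 0.8)
  expect_gte(sens_down, 0.8)
  expect_lte(fdr, 0.1)
  # recovered slopes carry the planted sign and unit
  up <- tr$program == "up"
  expect_gt(mean(tr$slope[up]), 0.5)
})

test_that("null simulation keeps the q <= 0.05 call rate at the nominal level", {
  cfg <- sim_config(n_genes = 500, seed = 31,
                    timepoints_h = c(1, 24, 48, 72),
                    frac_age_up = 0, frac_age_down = 0, frac_transient = 0,
                    frac_oscillatory = 0, frac_drift = 0)
  sim <- simulate_timecourse(cfg)
  nn <- normalize_counts(prefilter(sim$counts))
  tt <- trend_test(nn$normalized, sim$metadata$timepoint_h / 24)
  se <- sqrt(0.05 * 0.95 / nrow(tt))
  expect_lte(mean(tt$q <= 0.05), 0.05 + 2 * se)
})

test_that("trajectory clustering recovers planted archetypes", {
  f <- make_archetype_fixture(seed = 1)
  cl <- cluster_profiles(f$mat, f$times, k_range = 1:8, seed = 1)
  expect_true(all(diff(cl$wcss$wcss) <= 1e-8))
  ari <- adjusted_rand(cl$assignments_by_k$k4, f$labels)
  expect_gte(ari, 0.9)
  # the helper's adjusted Rand agrees with an independent implementation
  expect_equal(ari,
               mclust::adjustedRandIndex(cl$assignments_by_k$k4, f$labels),
               tolerance = 1e-12)
  # determinism under the seed
  cl2 <- cluster_profiles(f$mat, f$times, k_range = 1:8, seed = 1)
  expect_identical(cl$clusters, cl2$clusters)
  expect_identical(cl$wcss, cl2$wcss)
})

test_that("clustering handles degenerate inputs per contract", {
  f <- make_archetype_fixture(seed = 2, n_per = 10)
  expect_warning(
    single <- cluster_profiles(f$mat, f$times, k_range = 1),
    "elbow")
  expect_true(all(single$clusters$cluster == 1))
  flat <- f$mat
  flat[3, ] <- 5
  expect_warning(cluster_profiles(flat, f$times, k_range = 1:4, seed = 1),
                 "zero variance")
})

test_that("overlap concordance matches signed-set construction", {
  a <- data.frame(gene_id = c("g1", "g2", "g3"),
                  direction = c("up", "down", "up"))
  same <- exit_overlap(list(x = a, y = a))
  expect_equal(same$n_shared["x", "y"], 3L)
  expect_equal(same$frac_same_direction["x", "y"], 1)
  flipped <- a
  flipped$direction <- c("down", "up", "down")
  opp <- exit_overlap(list(x = a, y = flipped))
  expect_equal(opp$frac_same_direction["x", "y"], 0)
  disj <- exit_overlap(list(
    x = a, y = data.frame(gene_id = "g9", direction = "up")))
  expect_equal(disj$n_shared["x", "y"], 0L)
  expect_true(is.na(disj$frac_same_direction["x", "y"]))
  # symmetry
  part <- data.frame(gene_id = c("g2", "g3", "g4"),
                     direction = c("down", "down", "up"))
  ov <- exit_overlap(list(x = a, y = part))
  expect_equal(ov$n_shared, t(ov$n_shared))
  expect_equal(ov$frac_same_direction, t(ov$frac_same_direction))
  expect_equal(ov$frac_same_direction["x", "y"], 0.5)
})

test_that("PCA embedding separates duplicated sample groups reproducibly", {
  set.seed(5)
  base1 <- rgamma(100, 5, 0.05)
  base2 <- base1 * c(rep(8, 50), rep(1 / 8, 50))
  m <- cbind(a1 = base1, a2 = base1 * 1.01, a3 = base1 * 0.99,
             b1 = base2, b2 = base2 * 1.01, b3 = base2 * 0.99)
  rownames(m) <- sprintf("g%03d", 1:100)
  p <- pca_embed(m, n_components = 2)
  expect_true(all(sign(p$scores[1:3, 1]) != sign(p$scores[4:6, 1])))
  expect_gt(p$var_explained[1], 0.95)
  expect_lte(sum(p$var_explained), 1)
  # orientation convention: the largest-magnitude loading is positive
  for (j in 1:2) {
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  }
  expect_warning(pca_embed(m, n_components = 10), "truncating")
})

test_that("two-group DE slope is the log2 fold change between groups", {
  m <- rbind(up4x = c(100, 100, 100, 400, 400, 400),
             flat = c(200, 200, 200, 200, 200, 200))
  colnames(m) <- paste0("s", 1:6)
  de <- de_two_group(m, rep(c("ctl", "uv"), each = 3))
  expect_equal(de$slope[1], log2(400.5 / 100.5), tolerance = 1e-12)
  expect_equal(de$slope[2], 0)
  expect_error(de_two_group(m, rep("ctl", 6)), "2 levels")
})
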