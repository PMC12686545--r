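# Shared fixture builders and independent oracles. Everything is generated in
# code at test time; seeds are fixed so expected values are stable.

# Brute-force hypergeometric upper-tail p: enumerate every size-n draw from a
# universe of size N whose first m elements are the set, and count draws with
# overlap >= k. Independent of stats::phyper.
ora_brute_p <- function(N, m, n, k) {
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(q) sum(q <= m) >= k))
}

# Brute-force Mann-Whitney two-sided p: enumerate all labelings of the pooled
# values, build the exact null distribution of U, and take twice the smaller
# tail (capped at 1) around the observed U.
mwu_brute_p <- function(x, y) {
  nx <- length(x)
  pool <- c(x, y)
  r <- rank(pool)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(length(pool), nx)
  us <- apply(idx, 2, function(i) sum(r[i]) - nx * (nx + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Planted-trend fixture: only monotone programs, strong effect over a short
# (4-day) course, 3 replicates -- the conditions for sensitivity/FDR checks.
sim_trend_recovery <- function(seed = 11, n_genes = 500) {
  cfg <- sim_config(
    n_genes = n_genes, seed = seed,
    timepoints_h = c(1, 24, 48, 72),
    frac_age_up = 0.1, frac_age_down = 0.1,
    frac_transient = 0, frac_oscillatory = 0, frac_drift = 0,
    effect_size_log2_per_day = 1.0, nb_dispersion = 0.1
  )
  simulate_timecourse(cfg)
}

# Lifespan-cohort fixture for clock training: 4 cohorts x 5 timepoints x 3
# replicates = 60 samples, 500 genes, 20% age-responsive.
sim_clock_cohorts <- function(seed = 5) {
  simulate_lifespan_cohorts(
    sim_config(n_genes = 500, seed = seed,
               timepoints_h = c(24, 96, 240, 480, 720),
               frac_age_up = 0.1, frac_age_down = 0.1,
               effect_size_log2_per_day = 0.3, nb_dispersion = 0.1),
    n_cohorts = 4, lifespan_range_h = c(400, 1200)
  )
}

# Four planted trajectory archetypes (monotone up/down, early peak, late
# peak) with small Gaussian noise, 3 replicates per timepoint.
make_archetype_fixture <- function(seed = 1, n_per = 50, noise = 0.25) {
  set.seed(seed)
  tp <- c(1, 4, 15, 30)
  arche <- rbind(up = c(-1.3, -0.6, 0.5, 1.4),
                 down = c(1.4, 0.5, -0.6, -1.3),
                 early_peak = c(-0.7, 1.6, -0.2, -0.7),
                 late_peak = c(-0.7, -0.2, 1.6, -0.7))
  lab <- rep(rownames(arche), each = n_per)
  mat <- arche[lab, rep(1:4, each = 3)] +
    matrix(stats::rnorm(4 * n_per * 12, sd = noise), 4 * n_per, 12)
  mat <- mat - min(mat) + 0.01
  rownames(mat) <- sprintf("g%03d", seq_len(nrow(mat)))
  colnames(mat) <- sprintf("s%02d", 1:12)
  list(mat = mat, labels = lab, times = rep(tp, each = 3))
}

# Adjusted Rand index between two labelings (permutation-invariant cluster
# agreement); standard closed form from the pair-counting contingency table.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
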