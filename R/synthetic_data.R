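#' Simulation configuration for dauer-style RNA-seq time courses
#'
#' Bundles and validates every knob of the count simulator. Defaults emulate
#' the design the downstream analyses assume: 2,000 genes, 3 replicates at
#' dauer days 1/4/15/30 (24/96/360/720 h), negative-binomial counts with a
#' shared dispersion, log-normal library sizes, and five gene programs
#' (age-up, age-down, transient, oscillatory, drift) on top of a flat
#' background.
#'
#' @param n_genes Number of genes.
#' @param n_samples_per_timepoint Replicates per timepoint.
#' @param timepoints_h Strictly increasing chronological ages, in hours.
#' @param seed Integer seed; all randomness in the simulator derives from it.
#' @param library_size_mean Expected total counts per sample.
#' @param library_size_cv Coefficient of variation of the log-normal library
#'   sizes.
#' @param frac_age_up,frac_age_down,frac_transient,frac_oscillatory,frac_drift
#'   Fractions of genes assigned to each program; must sum to at most 1, the
#'   remainder is flat.
#' @param effect_size_log2_per_day Slope magnitude, in log2 units per day of
#'   age, for the monotone programs (also scales the transient bump). The
#'   0.2 default corresponds to a ~64-fold cumulative change over a 30-day
#'   course, the scale of strongly age-regulated genes; short fixtures
#'   (a few days) typically use 1.0.
#' @param osc_amplitude_log2 Amplitude of the oscillatory program (log2 units).
#' @param osc_period_h Period of the oscillatory program, in hours. The 8 h
#'   default mimics developmental expression oscillations.
#' @param drift_rate_per_day Hazard, per day of age, of a drift gene switching
#'   from its low baseline to its high state in a given sample.
#' @param drift_jump_log2 Expression increase (log2 units) of a switched-on
#'   drift gene.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); must be > 0.
#' @param uv_dose Default UV dose (arbitrary units, >= 0) used by
#'   [apply_uv_effect()] when no dose is given.
#' @param lesion_rate_per_kb_per_dose Transcription-blocking lesion rate per kb
#'   of gene length per dose unit.
#' @param gene_length_range_bp Length-2 vector; gene lengths are drawn
#'   log-uniformly over this range (bp).
#' @return An object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_genes = 2000L,
                       n_samples_per_timepoint = 3L,
                       timepoints_h = c(24, 96, 360, 720),
                       seed = 1L,
                       library_size_mean = 2e6,
                       library_size_cv = 0.2,
                       frac_age_up = 0.05,
                       frac_age_down = 0.05,
                       frac_transient = 0.05,
                       frac_oscillatory = 0.05,
                       frac_drift = 0.05,
                       effect_size_log2_per_day = 0.2,
                       osc_amplitude_log2 = 1.0,
                       osc_period_h = 8,
                       drift_rate_per_day = 0.05,
                       drift_jump_log2 = 4,
                       nb_dispersion = 0.1,
                       uv_dose = 0,
                       lesion_rate_per_kb_per_dose = 0,
                       gene_length_range_bp = c(200, 1e5)) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_samples_per_timepoint = as.integer(n_samples_per_timepoint),
    timepoints_h = as.numeric(timepoints_h),
    seed = as.integer(seed),
    library_size_mean = library_size_mean,
    library_size_cv = library_size_cv,
    frac_age_up = frac_age_up,
    frac_age_down = frac_age_down,
    frac_transient = frac_transient,
    frac_oscillatory = frac_oscillatory,
    frac_drift = frac_drift,
    effect_size_log2_per_day = effect_size_log2_per_day,
    osc_amplitude_log2 = osc_amplitude_log2,
    osc_period_h = osc_period_h,
    drift_rate_per_day = drift_rate_per_day,
    drift_jump_log2 = drift_jump_log2,
    nb_dispersion = nb_dispersion,
    uv_dose = uv_dose,
    lesion_rate_per_kb_per_dose = lesion_rate_per_kb_per_dose,
    gene_length_range_bp = as.numeric(gene_length_range_bp)
  )
  if (cfg$n_genes < 1L) stop("n_genes must be >= 1", call. = FALSE)
  if (cfg$n_samples_per_timepoint < 1L) {
    stop("n_samples_per_timepoint must be >= 1", call. = FALSE)
  }
  if (length(cfg$timepoints_h) < 1L || any(diff(cfg$timepoints_h) <= 0)) {
    stop("timepoints_h must be strictly increasing", call. = FALSE)
  }
  fr <- c(cfg$frac_age_up, cfg$frac_age_down, cfg$frac_transient,
          cfg$frac_oscillatory, cfg$frac_drift)
  if (any(fr < 0) || sum(fr) > 1 + 1e-12) {
    stop("program fractions must be non-negative and sum to at most 1",
         call. = FALSE)
  }
  if (!is.finite(cfg$nb_dispersion) || cfg$nb_dispersion <= 0) {
    stop("nb_dispersion must be > 0", call. = FALSE)
  }
  if (cfg$uv_dose < 0) stop("uv_dose must be >= 0", call. = FALSE)
  if (cfg$lesion_rate_per_kb_per_dose < 0) {
    stop("lesion_rate_per_kb_per_dose must be >= 0", call. = FALSE)
  }
  if (length(cfg$gene_length_range_bp) != 2L ||
      cfg$gene_length_range_bp[1] <= 0 ||
      diff(cfg$gene_length_range_bp) < 0) {
    stop("gene_length_range_bp must be an increasing positive pair", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# Assign one program label per gene, seeded shuffle so label sets are
# reproducible and disjoint.
.assign_programs <- function(cfg) {
  n <- cfg$n_genes
  n_per <- c(
    up = round(cfg$frac_age_up * n),
    down = round(cfg$frac_age_down * n),
    transient = round(cfg$frac_transient * n),
    oscillatory = round(cfg$frac_oscillatory * n),
    drift = round(cfg$frac_drift * n)
  )
  program <- rep("flat", n)
  idx <- sample.int(n)
  pos <- 1L
  for (p in names(n_per)) {
    if (n_per[[p]] > 0) {
      program[idx[pos:(pos + n_per[[p]] - 1L)]] <- p
      pos <- pos + n_per[[p]]
    }
  }
  program
}

# Per-gene log2 expression offset at a given biological age (hours) for the
# deterministic programs; drift is sampled per sample elsewhere.
.program_offset <- function(program, age_h, cfg) {
  age_d <- age_h / 24
  span_d <- diff(range(cfg$timepoints_h)) / 24
  mid_d <- mean(range(cfg$timepoints_h)) / 24
  sigma_d <- max(span_d / 4, 1e-9)
  eff <- cfg$effect_size_log2_per_day
  switch(program,
    up = eff * age_d,
    down = -eff * age_d,
    transient = eff * (span_d / 2) * exp(-0.5 * ((age_d - mid_d) / sigma_d)^2),
    oscillatory = cfg$osc_amplitude_log2 * sin(2 * pi * age_h / cfg$osc_period_h),
    0
  )
}

# Draw a counts matrix given per-sample biological ages. Returns counts with
# the expected-value matrix and dispersion attached so UV redraws can reuse
# the true means.
.draw_counts <- function(cfg, genes, bio_age_h, sample_ids) {
  n <- cfg$n_genes
  s <- length(bio_age_h)
  offset <- matrix(0, n, s)
  for (j in seq_len(s)) {
    offset[, j] <- vapply(genes$program, .program_offset,
                          numeric(1), age_h = bio_age_h[j], cfg = cfg)
  }
  drift <- genes$program == "drift"
  if (any(drift)) {
    p_on <- 1 - exp(-cfg$drift_rate_per_day * (bio_age_h / 24))
    on <- matrix(stats::rbinom(sum(drift) * s, 1L,
                               rep(p_on, each = sum(drift))), sum(drift), s)
    offset[drift, ] <- offset[drift, ] + on * cfg$drift_jump_log2
  }
  sdlog <- sqrt(log(1 + cfg$library_size_cv^2))
  lib <- stats::rlnorm(s, log(cfg$library_size_mean) - sdlog^2 / 2, sdlog)
  w <- genes$baseline * 2^offset
  q <- sweep(w, 2, colSums(w), "/")
  mu <- sweep(q, 2, lib, "*")
  counts <- matrix(stats::rnbinom(n * s, mu = mu, size = 1 / cfg$nb_dispersion),
                   n, s, dimnames = list(genes$gene_id, sample_ids))
  storage.mode(counts) <- "integer"
  attr(counts, "mu") <- mu
  attr(counts, "nb_dispersion") <- cfg$nb_dispersion
  counts
}

.make_genes <- function(cfg) {
  n <- cfg$n_genes
  gene_id <- sprintf("g%05d", seq_len(n))
  program <- .assign_programs(cfg)
  rng <- log(cfg$gene_length_range_bp)
  length_bp <- round(exp(stats::runif(n, rng[1], rng[2])))
  baseline <- stats::rlnorm(n, meanlog = log(50), sdlog = 1.2)
  # drift genes start low so their binarized state is 0 when young
  baseline[program == "drift"] <- baseline[program == "drift"] * 0.1
  eff <- cfg$effect_size_log2_per_day
  true_slope <- ifelse(program == "up", eff, ifelse(program == "down", -eff, 0))
  data.frame(gene_id = gene_id, program = program, true_slope = true_slope,
             length_bp = length_bp, retention = 1,
             baseline = baseline, stringsAsFactors = FALSE)
}

#' Simulate a dauer-aging RNA-seq time course
#'
#' Draws negative-binomial counts for a gene-by-sample matrix in which
#' age-monotone genes change their mean by
#' \code{effect_size_log2_per_day * age_days}, transient genes peak at the
#' interior of the time course, oscillatory genes follow a sinusoid, and drift
#' genes switch stochastically from a low baseline to a high state with a
#' per-day hazard. Library sizes are log-normal; output is deterministic for a
#' fixed seed.
#'
#' @param config A [sim_config()] object.
#' @return List with elements \code{counts} (integer matrix, with attributes
#'   \code{mu} and \code{nb_dispersion} recording the generating means),
#'   \code{metadata} (per-sample data.frame), and \code{truth} (ground-truth
#'   list with per-gene programs, slopes, lengths, retention and per-sample
#'   true biological age).
#' @examples
#' sim <- simulate_timecourse(sim_config(n_genes = 200, seed = 7))
#' dim(sim$counts)
#' @export
simulate_timecourse <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- .make_genes(config)
  tp <- rep(config$timepoints_h, each = config$n_samples_per_timepoint)
  rep_id <- rep(seq_len(config$n_samples_per_timepoint),
                times = length(config$timepoints_h))
  sample_ids <- sprintf("d%03g_r%d", tp / 24, rep_id)
  counts <- .draw_counts(config, genes, bio_age_h = tp, sample_ids = sample_ids)
  metadata <- data.frame(
    sample_id = sample_ids,
    group = sprintf("D%g", tp / 24),
    timepoint_h = tp,
    median_lifespan_h = NA_real_,
    stringsAsFactors = FALSE
  )
  truth <- structure(list(
    genes = genes[, c("gene_id", "program", "true_slope", "length_bp", "retention")],
    samples = data.frame(sample_id = sample_ids, true_bioage_h = tp,
                         stringsAsFactors = FALSE),
    config = config
  ), class = "sim_truth")
  list(counts = counts, metadata = metadata, truth = truth)
}

#' Simulate lifespan-labeled cohorts for clock training
#'
#' Generates several cohorts sampled at the same chronological timepoints but
#' with different median lifespans. Expression depends on \emph{biological}
#' age — chronological age rescaled by the ratio of the reference lifespan
#' (the mean of the drawn cohort lifespans) to the cohort's lifespan — so a
#' clock trained across cohorts must learn lifespan-invariant signal. By
#' construction, a long-lived cohort at chronological age \code{a} has the
#' same expected expression as a cohort with half its lifespan at \code{a/2}.
#'
#' @param config A [sim_config()] object; its timepoints are the chronological
#'   sampling ages of every cohort.
#' @param n_cohorts Number of cohorts (>= 2).
#' @param lifespan_range_h Length-2 vector of positive bounds; cohort median
#'   lifespans are drawn uniformly over this range.
#' @return As [simulate_timecourse()], with \code{median_lifespan_h} filled in
#'   per cohort and \code{truth$samples$true_bioage_h} holding the rescaled
#'   biological ages. \code{truth$reference_lifespan_h} records the reference.
#' @export
simulate_lifespan_cohorts <- function(config, n_cohorts = 4L,
                                      lifespan_range_h = c(400, 1200)) {
  stopifnot(inherits(config, "sim_config"))
  if (n_cohorts < 2L) stop("n_cohorts must be >= 2", call. = FALSE)
  if (lifespan_range_h[1] <= 0 || diff(lifespan_range_h) < 0) {
    stop("lifespan_range_h lower bound must be > 0 and range non-decreasing",
         call. = FALSE)
  }
  set.seed(config$seed)
  genes <- .make_genes(config)
  lifespans <- stats::runif(n_cohorts, lifespan_range_h[1], lifespan_range_h[2])
  reference <- mean(lifespans)
  tp <- rep(config$timepoints_h, each = config$n_samples_per_timepoint)
  rep_id <- rep(seq_len(config$n_samples_per_timepoint),
                times = length(config$timepoints_h))
  md <- do.call(rbind, lapply(seq_len(n_cohorts), function(co) {
    data.frame(
      sample_id = sprintf("c%d_d%03g_r%d", co, tp / 24, rep_id),
      group = sprintf("cohort%d", co),
      timepoint_h = tp,
      median_lifespan_h = lifespans[co],
      stringsAsFactors = FALSE
    )
  }))
  bio <- md$timepoint_h * reference / md$median_lifespan_h
  counts <- .draw_counts(config, genes, bio_age_h = bio,
                         sample_ids = md$sample_id)
  truth <- structure(list(
    genes = genes[, c("gene_id", "program", "true_slope", "length_bp", "retention")],
    samples = data.frame(sample_id = md$sample_id, true_bioage_h = bio,
                         stringsAsFactors = FALSE),
    reference_lifespan_h = reference,
    config = config
  ), class = "sim_truth")
  list(counts = counts, metadata = md, truth = truth)
}

#' Apply a UV transcription-block effect to simulated counts
#'
#' Models gene-length-dependent transcription decline after UV irradiation:
#' each gene's expected count is multiplied by a retention factor
#' \code{exp(-lesion_rate * dose * length_kb)} — the probability that a
#' transcript of that length escapes a transcription-blocking lesion — and
#' counts are re-drawn from the negative binomial. Dose 0 leaves the
#' generating distribution unchanged.
#'
#' @param counts Simulated counts carrying a \code{mu} attribute (as returned
#'   by the simulators); plain counts are accepted and then treated as the
#'   expected values.
#' @param truth Matching \code{sim_truth} (provides gene lengths).
#' @param dose UV dose (>= 0).
#' @param lesion_rate_per_kb_per_dose Lesion rate per kb per dose unit.
#' @param seed Optional seed for the redraw.
#' @return Integer count matrix with updated \code{mu} and a
#'   \code{retention} attribute (per-gene factors in (0, 1]).
#' @export
apply_uv_effect <- function(counts, truth, dose,
                            lesion_rate_per_kb_per_dose, seed = NULL) {
  .assert_count_matrix(counts)
  stopifnot(inherits(truth, "sim_truth"))
  .assert_scalar_number(dose, "dose")
  if (dose < 0) stop("dose must be >= 0", call. = FALSE)
  if (lesion_rate_per_kb_per_dose < 0) {
    stop("lesion_rate_per_kb_per_dose must be >= 0", call. = FALSE)
  }
  lengths_kb <- truth$genes$length_bp[match(rownames(counts),
                                            truth$genes$gene_id)] / 1000
  if (anyNA(lengths_kb)) {
    stop("counts contain genes absent from truth$genes", call. = FALSE)
  }
  retention <- exp(-lesion_rate_per_kb_per_dose * dose * lengths_kb)
  mu <- attr(counts, "mu")
  if (is.null(mu)) mu <- counts
  disp <- attr(counts, "nb_dispersion")
  if (is.null(disp)) disp <- truth$config$nb_dispersion
  if (!is.null(seed)) set.seed(seed)
  mu_uv <- mu * retention
  out <- matrix(stats::rnbinom(length(mu_uv), mu = mu_uv, size = 1 / disp),
                nrow(counts), ncol(counts), dimnames = dimnames(counts))
  storage.mode(out) <- "integer"
  attr(out, "mu") <- mu_uv
  attr(out, "nb_dispersion") <- disp
  attr(out, "retention") <- stats::setNames(retention, rownames(counts))
  out
}

#' Build gene sets from simulation ground truth
#'
#' One set per non-flat program (its member genes) plus random background sets,
#' so over-representation analysis on recovered differentially expressed genes
#' has planted positives and nulls.
#'
#' @param truth A \code{sim_truth} object.
#' @param n_random Number of random background sets.
#' @param random_set_size Genes per random set.
#' @param seed Seed for the random sets.
#' @return A \code{gene_set_collection} (see [read_gmt()]).
#' @export
build_program_genesets <- function(truth, n_random = 20L,
                                   random_set_size = 25L, seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  g <- truth$genes
  sets <- split(g$gene_id, g$program)
  sets <- sets[setdiff(names(sets), "flat")]
  names(sets) <- paste0("program_", names(sets))
  set.seed(seed)
  for (i in seq_len(n_random)) {
    sets[[sprintf("random_%02d", i)]] <-
      sample(g$gene_id, min(random_set_size, nrow(g)))
  }
  descr <- stats::setNames(rep("synthetic gene set", length(sets)), names(sets))
  structure(list(sets = sets, description = descr),
            class = "gene_set_collection")
}

#' Write a simulated fixture to a directory
#'
#' Writes \code{counts.tsv}, \code{metadata.tsv}, \code{genes.tsv},
#' \code{truth.tsv}, \code{truth_samples.tsv} and (optionally)
#' \code{genesets.gmt}; [read_fixture()] restores the objects.
#'
#' @param dir Output directory (created if needed).
#' @param counts,metadata,truth As returned by the simulators.
#' @param genesets Optional \code{gene_set_collection}.
#' @return \code{dir}, invisibly.
#' @export
write_fixture <- function(dir, counts, metadata, truth, genesets = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(counts, file.path(dir, "counts.tsv"))
  write_tsv(metadata, file.path(dir, "metadata.tsv"))
  write_tsv(truth$genes[, c("gene_id", "length_bp")], file.path(dir, "genes.tsv"))
  write_tsv(truth$genes[, c("gene_id", "program", "true_slope", "retention")],
            file.path(dir, "truth.tsv"))
  write_tsv(truth$samples, file.path(dir, "truth_samples.tsv"))
  if (!is.null(genesets)) write_gmt(genesets, file.path(dir, "genesets.gmt"))
  invisible(dir)
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param dir Fixture directory.
#' @return List with \code{counts}, \code{metadata}, \code{truth} and, when
#'   present, \code{genesets}.
#' @export
read_fixture <- function(dir) {
  counts <- read_counts(file.path(dir, "counts.tsv"))
  metadata <- read_metadata(file.path(dir, "metadata.tsv"))
  genes <- utils::read.delim(file.path(dir, "genes.tsv"), stringsAsFactors = FALSE)
  tr <- utils::read.delim(file.path(dir, "truth.tsv"), stringsAsFactors = FALSE)
  samples <- utils::read.delim(file.path(dir, "truth_samples.tsv"),
                               stringsAsFactors = FALSE)
  truth <- structure(list(
    genes = merge(tr, genes, by = "gene_id",
                  sort = FALSE)[, c("gene_id", "program", "true_slope",
                                    "length_bp", "retention")],
    samples = samples,
    config = NULL
  ), class = "sim_truth")
  out <- list(counts = counts, metadata = metadata, truth = truth)
  gmt <- file.path(dir, "genesets.gmt")
  if (file.exists(gmt)) out$genesets <- read_gmt(gmt)
  out
}
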