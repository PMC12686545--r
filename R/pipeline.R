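#' Read a pipeline configuration from YAML
#'
#' Missing fields take the defaults of [run_pipeline()]'s config; see that
#' function for the recognized fields.
#'
#' @param path Path to a YAML config.
#' @return Named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

.default_config <- function() {
  list(
    seed = 1L,
    alpha = 0.05,
    outdir = "dauerclock_out",
    simulate = list(),           # sim_config() arguments; NULL disables
    counts = NULL, metadata = NULL, genes = NULL, gmt = NULL,
    stages = list(clock = TRUE, stochastic = TRUE, trend = TRUE,
                  cluster = TRUE, overlap = TRUE, enrich = TRUE,
                  gltd = TRUE, pca = TRUE),
    clock = list(cv_folds = 5L, alpha = 0.5, n_cohorts = 4L,
                 lifespan_range_h = c(400, 1200)),
    stochastic = list(n_genes = 50L),
    k_range = 2:8,
    uv = list(dose = 1, lesion_rate_per_kb_per_dose = 0.1)
  )
}

.merge_config <- function(user) {
  cfg <- .default_config()
  for (nm in names(user)) {
    if (is.list(cfg[[nm]]) && is.list(user[[nm]])) {
      for (sub in names(user[[nm]])) cfg[[nm]][[sub]] <- user[[nm]][[sub]]
    } else {
      cfg[[nm]] <- user[[nm]]
    }
  }
  cfg
}

.run_stage <- function(name, manifest_env, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  message(sprintf("[dauerclock] stage %-10s done in %.2fs", name, elapsed))
  manifest_env$stages[[name]] <- list(elapsed_s = elapsed)
  res
}

#' Run the full dauer transcriptome pipeline
#'
#' Orchestrates simulate (optional) -> prefilter -> normalize -> clocks ->
#' trend -> cluster -> overlap -> enrich -> GLTD and writes every stage's
#' table plus a JSON run manifest (inputs, seeds, package version, per-file
#' MD5 hashes) to the output directory. Rerunning with the same config
#' reproduces identical hashes. With the default config the pipeline runs a
#' self-contained demo on simulated data: a dauer-aging time course for the
#' trend/cluster/enrichment stages, lifespan-labeled cohorts for clock
#' training with one held-out cohort, and a UV-treated redraw of the time
#' course for the GLTD stage.
#'
#' @param config Named list (or path handled by [read_pipeline_config()]).
#'   Recognized fields: \code{seed}, \code{alpha}, \code{outdir},
#'   \code{simulate} (arguments to [sim_config()]; set to \code{NULL} and
#'   give \code{counts}/\code{metadata}/\code{genes}/\code{gmt} paths to run
#'   on existing files), \code{stages} (named logical toggles: clock,
#'   stochastic, trend, cluster, overlap, enrich, gltd, pca), \code{clock}
#'   (cv_folds, alpha, n_cohorts, lifespan_range_h), \code{stochastic}
#'   (n_genes), \code{k_range}, \code{uv} (dose,
#'   lesion_rate_per_kb_per_dose).
#' @return The manifest list, invisibly; also written as
#'   \code{manifest.json}.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- .merge_config(config)
  outdir <- cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  env <- new.env()
  env$stages <- list()
  skipped <- character()
  outputs <- character()
  add_out <- function(path) {
    outputs <<- c(outputs, path)
    path
  }

  simulate <- !is.null(cfg$simulate)
  if (simulate) {
    sim <- .run_stage("simulate", env, {
      scfg <- do.call(sim_config, c(cfg$simulate, list(seed = cfg$seed)))
      simulate_timecourse(scfg)
    })
    counts <- sim$counts
    metadata <- sim$metadata
    truth <- sim$truth
    genesets <- build_program_genesets(truth, seed = cfg$seed)
    fixdir <- file.path(outdir, "fixture")
    write_fixture(fixdir, counts, metadata, truth, genesets)
    add_out(file.path(fixdir, c("counts.tsv", "metadata.tsv", "genes.tsv",
                                "truth.tsv", "truth_samples.tsv",
                                "genesets.gmt")))
    lengths <- stats::setNames(truth$genes$length_bp, truth$genes$gene_id)
  } else {
    for (field in c("counts", "metadata")) {
      if (is.null(cfg[[field]])) {
        stop("config field '", field, "' is required when not simulating",
             call. = FALSE)
      }
    }
    counts <- read_counts(cfg$counts)
    metadata <- read_metadata(cfg$metadata)
    truth <- NULL
    genesets <- if (!is.null(cfg$gmt)) read_gmt(cfg$gmt) else NULL
    lengths <- if (!is.null(cfg$genes)) {
      g <- utils::read.delim(cfg$genes, stringsAsFactors = FALSE)
      stats::setNames(g$length_bp, g$gene_id)
    } else NULL
  }

  filtered <- .run_stage("prefilter", env, prefilter(counts))
  norm <- .run_stage("normalize", env, normalize_counts(filtered))
  write_tsv(data.frame(sample_id = names(norm$size_factors),
                       size_factor = unname(norm$size_factors)),
            add_out(file.path(outdir, "size_factors.tsv")))
  times <- metadata$timepoint_h[match(colnames(counts), metadata$sample_id)]

  trend <- NULL
  if (isTRUE(cfg$stages$trend)) {
    trend <- .run_stage("trend", env,
                        trend_test(norm$normalized, times / 24,
                                   alpha = cfg$alpha))
    write_tsv(trend, add_out(file.path(outdir, "trend.tsv")))
  } else skipped <- c(skipped, "trend")

  if (isTRUE(cfg$stages$cluster) && !is.null(trend)) {
    cl <- .run_stage("cluster", env, {
      sig <- trend$gene_id[trend$direction != "ns"]
      mat <- if (length(sig) >= max(cfg$k_range) * 3) {
        norm$normalized[sig, , drop = FALSE]
      } else norm$normalized
      cluster_profiles(mat, times, k_range = cfg$k_range, seed = cfg$seed)
    })
    write_tsv(cl$clusters, add_out(file.path(outdir, "clusters.tsv")))
    write_tsv(cl$wcss, add_out(file.path(outdir, "wcss.tsv")))
  } else skipped <- c(skipped, if (!isTRUE(cfg$stages$cluster)) "cluster")

  if (isTRUE(cfg$stages$pca)) {
    pca <- .run_stage("pca", env, pca_embed(norm$normalized))
    write_tsv(data.frame(sample_id = rownames(pca$scores), pca$scores),
              add_out(file.path(outdir, "pca_scores.tsv")))
  } else skipped <- c(skipped, "pca")

  if (isTRUE(cfg$stages$clock) && simulate) {
    clockres <- .run_stage("clock", env, {
      coh <- simulate_lifespan_cohorts(
        do.call(sim_config, c(cfg$simulate, list(seed = cfg$seed + 1L))),
        n_cohorts = cfg$clock$n_cohorts,
        lifespan_range_h = cfg$clock$lifespan_range_h)
      holdout <- coh$metadata$group == coh$metadata$group[nrow(coh$metadata)]
      bin <- binarize(coh$counts)
      model <- train_clock(bin[, !holdout, drop = FALSE],
                           coh$truth$samples$true_bioage_h[!holdout],
                           cv_folds = cfg$clock$cv_folds,
                           alpha = cfg$clock$alpha, seed = cfg$seed)
      pba_hold <- predict_age(bin[, holdout, drop = FALSE], model)
      pba_dauer <- predict_age(binarize(counts), model)
      list(model = model, pba_holdout = pba_hold, pba = pba_dauer,
           holdout_true = coh$truth$samples$true_bioage_h[holdout])
    })
    write_clock_model(clockres$model, add_out(file.path(outdir, "clock.json")))
    write_tsv(clockres$pba, add_out(file.path(outdir, "pba.tsv")))
    tp <- sort(unique(times))
    mean_pba <- vapply(tp, function(a) {
      mean(clockres$pba$predicted_biological_age_h[times == a])
    }, numeric(1))
    rates <- data.frame(
      from_h = utils::head(tp, -1), to_h = utils::tail(tp, -1),
      rate = aging_rate(utils::head(mean_pba, -1), utils::tail(mean_pba, -1),
                        utils::head(tp, -1), utils::tail(tp, -1)))
    write_tsv(rates, add_out(file.path(outdir, "aging_rates.tsv")))
  } else skipped <- c(skipped, if (!isTRUE(cfg$stages$clock)) "clock")

  if (isTRUE(cfg$stages$stochastic) && simulate) {
    sto <- .run_stage("stochastic", env, {
      model <- select_clock_genes(counts, times,
                                  n_genes = cfg$stochastic$n_genes)
      list(model = model, scores = stochastic_score(counts, model))
    })
    write_stochastic_model(sto$model,
                           add_out(file.path(outdir, "stochastic_model.json")))
    write_tsv(sto$scores, add_out(file.path(outdir, "stochastic_scores.tsv")))
  } else skipped <- c(skipped,
                      if (!isTRUE(cfg$stages$stochastic)) "stochastic")

  uv_trend <- NULL
  if ((isTRUE(cfg$stages$gltd) || isTRUE(cfg$stages$overlap)) &&
      simulate && !is.null(lengths)) {
    uv_trend <- .run_stage("uv_de", env, {
      uv <- apply_uv_effect(counts, truth, dose = cfg$uv$dose,
                            lesion_rate_per_kb_per_dose =
                              cfg$uv$lesion_rate_per_kb_per_dose,
                            seed = cfg$seed + 2L)
      both <- cbind(counts, uv)
      colnames(both) <- c(paste0(colnames(counts), "_ctl"),
                          paste0(colnames(counts), "_uv"))
      grp <- rep(c("ctl", "uv"), each = ncol(counts))
      bn <- normalize_counts(prefilter(both))
      de_two_group(bn$normalized, grp, alpha = cfg$alpha)
    })
  }

  if (isTRUE(cfg$stages$overlap) && !is.null(trend) && !is.null(uv_trend)) {
    ov <- .run_stage("overlap", env, {
      exit_overlap(list(
        dauer_aging = trend[trend$direction != "ns",
                            c("gene_id", "direction")],
        uv_response = uv_trend[uv_trend$direction != "ns",
                               c("gene_id", "direction")]))
    })
    write_tsv(ov$pairs, add_out(file.path(outdir, "overlap.tsv")))
  } else skipped <- c(skipped, if (!isTRUE(cfg$stages$overlap)) "overlap")

  if (isTRUE(cfg$stages$enrich) && !is.null(trend) && !is.null(genesets)) {
    enr <- .run_stage("enrich", env, {
      ora(trend$gene_id[trend$direction == "up"], genesets,
          universe = rownames(filtered), cutoff = cfg$alpha)
    })
    write_tsv(enr, add_out(file.path(outdir, "enrichment.tsv")))
  } else skipped <- c(skipped, if (!isTRUE(cfg$stages$enrich)) "enrich")

  if (isTRUE(cfg$stages$gltd) && !is.null(uv_trend) && !is.null(lengths)) {
    gl <- .run_stage("gltd", env, {
      up <- uv_trend$gene_id[uv_trend$direction == "up"]
      down <- uv_trend$gene_id[uv_trend$direction == "down"]
      gltd_test(up, down, lengths)
    })
    write_tsv(data.frame(n_up = gl$n_up, n_down = gl$n_down,
                         median_length_up = gl$median_length_up,
                         median_length_down = gl$median_length_down,
                         U = gl$U, p = gl$p, direction = gl$direction),
              add_out(file.path(outdir, "gltd.tsv")))
  } else skipped <- c(skipped, if (!isTRUE(cfg$stages$gltd)) "gltd")

  outputs <- outputs[file.exists(outputs)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("dauerclock")),
    seed = cfg$seed,
    alpha = cfg$alpha,
    simulated = simulate,
    skipped = I(unique(skipped)),
    stages = env$stages,
    outputs = as.list(tools::md5sum(outputs))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
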