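#' Binarize a count matrix per sample
#'
#' Per sample, the threshold is the median of that sample's nonzero gene
#' values; a gene is set to 1 iff its value is strictly above the threshold.
#' Zero-count genes are excluded from the median computation and are always 0.
#' This is the binarization underlying both clocks.
#'
#' @param counts Non-negative gene-by-sample matrix (raw counts or any
#'   monotone per-sample transform of them).
#' @return Integer 0/1 matrix with the same dimnames as \code{counts}.
#' @examples
#' m <- matrix(c(0, 0, 5, 10, 20), ncol = 1,
#'             dimnames = list(paste0("g", 1:5), "s1"))
#' binarize(m)[, 1]  # only the value above the nonzero median (10) becomes 1
#' @export
binarize <- function(counts) {
  .assert_count_matrix(counts)
  out <- matrix(0L, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  for (j in seq_len(ncol(counts))) {
    x <- counts[, j]
    nz <- x[x > 0]
    if (length(nz) == 0L) {
      stop("sample '", colnames(counts)[j],
           "' has all-zero counts; nonzero median undefined", call. = FALSE)
    }
    out[, j] <- as.integer(x > stats::median(nz))
  }
  out
}

#' Rescale chronological age to biological age
#'
#' Maps chronological age onto a common timescale by the ratio of a reference
#' lifespan to the cohort's median lifespan:
#' \code{age * reference_lifespan_h / cohort_median_lifespan_h}. A cohort
#' living twice as long as the reference is biologically half as old at the
#' same chronological age.
#'
#' @param chronological_age_h Chronological age(s), hours.
#' @param cohort_median_lifespan_h Median lifespan of the sample's cohort,
#'   hours (> 0).
#' @param reference_lifespan_h Reference lifespan, hours (> 0).
#' @return Biological age(s) in hours.
#' @export
rescale_biological_age <- function(chronological_age_h,
                                   cohort_median_lifespan_h,
                                   reference_lifespan_h) {
  if (any(cohort_median_lifespan_h <= 0) || any(reference_lifespan_h <= 0)) {
    stop("lifespans must be > 0", call. = FALSE)
  }
  chronological_age_h * reference_lifespan_h / cohort_median_lifespan_h
}

#' Train a binarized-transcriptome aging clock
#'
#' Elastic-net linear regression of biological age (hours) on per-sample
#' binarized gene states, with the penalty strength chosen by k-fold
#' cross-validation minimizing mean squared error. Only genes with nonzero
#' coefficients are retained in the model. Deterministic for a fixed seed
#' (the seed fixes the CV fold assignment).
#'
#' @param binarized Gene-by-sample 0/1 matrix from [binarize()].
#' @param biological_ages_h Numeric vector of training labels, one per sample
#'   column (typically from [rescale_biological_age()]).
#' @param cv_folds Number of CV folds (default 5; must not exceed the number
#'   of samples).
#' @param alpha Elastic-net mixing parameter in [0, 1] (default 0.5).
#' @param seed Integer seed recorded in the model.
#' @return An object of class \code{clock_model}: list with
#'   \code{coefficients} (named numeric, hours contributed by each active
#'   gene), \code{intercept} (hours), \code{n_genes}, and \code{meta}
#'   (seed, folds, alpha, selected lambda, training size).
#' @export
train_clock <- function(binarized, biological_ages_h, cv_folds = 5L,
                        alpha = 0.5, seed = 1L) {
  .assert_count_matrix(binarized, "binarized")
  n <- ncol(binarized)
  if (length(biological_ages_h) != n) {
    stop("biological_ages_h must have one label per sample column", call. = FALSE)
  }
  if (length(unique(biological_ages_h)) < 2L) {
    stop("biological_ages_h must contain at least 2 distinct values", call. = FALSE)
  }
  if (cv_folds > n) stop("cv_folds exceeds the number of samples", call. = FALSE)
  if (cv_folds < 3L) stop("cv_folds must be >= 3", call. = FALSE)
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(cv_folds), n))
  fit <- glmnet::cv.glmnet(t(binarized), biological_ages_h,
                           alpha = alpha, foldid = foldid,
                           family = "gaussian", type.measure = "mse",
                           standardize = FALSE)
  cf <- as.matrix(stats::coef(fit, s = "lambda.min"))
  intercept <- cf["(Intercept)", 1]
  genes <- cf[-1, 1]
  genes <- genes[genes != 0]
  structure(list(
    coefficients = genes,
    intercept = unname(intercept),
    n_genes = length(genes),
    meta = list(seed = as.integer(seed), cv_folds = as.integer(cv_folds),
                alpha = alpha, lambda = fit$lambda.min, n_train = n)
  ), class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat("Binarized aging clock:", x$n_genes, "genes, intercept",
      sprintf("%.2f h", x$intercept), "\n")
  invisible(x)
}

#' Predict biological age from binarized samples
#'
#' The predicted biological age (PBA) of a sample is the sum of the clock
#' coefficients of the clock genes in state 1, plus the model intercept.
#' Clock genes absent from the query matrix are treated as state 0 (with a
#' warning), so models transfer across annotation versions.
#'
#' @param binarized Gene-by-sample 0/1 matrix, or a named 0/1 vector for a
#'   single sample.
#' @param model A \code{clock_model}.
#' @return data.frame with columns \code{sample_id} and
#'   \code{predicted_biological_age_h}.
#' @export
predict_age <- function(binarized, model) {
  stopifnot(inherits(model, "clock_model"))
  if (is.vector(binarized)) {
    binarized <- matrix(binarized, ncol = 1,
                        dimnames = list(names(binarized), "sample"))
  }
  genes <- names(model$coefficients)
  present <- genes %in% rownames(binarized)
  if (!all(present)) {
    warning(sum(!present), " clock gene(s) absent from query matrix; ",
            "treated as state 0", call. = FALSE)
  }
  state <- matrix(0, length(genes), ncol(binarized),
                  dimnames = list(genes, colnames(binarized)))
  state[present, ] <- binarized[genes[present], , drop = FALSE]
  pba <- drop(crossprod(state, model$coefficients)) + model$intercept
  data.frame(sample_id = colnames(binarized),
             predicted_biological_age_h = unname(pba),
             stringsAsFactors = FALSE)
}

#' Biological aging rate between two timepoints
#'
#' The dimensionless ratio of the change in predicted biological age to the
#' elapsed chronological time: \code{(pba_end - pba_start) / (chrono_end -
#' chrono_start)}. A rate of 1 means aging at the reference pace; values
#' below 1 indicate slowed biological aging.
#'
#' @param pba_start_h,pba_end_h Predicted biological ages (hours).
#' @param chrono_start_h,chrono_end_h Chronological ages (hours);
#'   \code{chrono_end_h} must exceed \code{chrono_start_h}.
#' @return Aging rate (dimensionless).
#' @examples
#' aging_rate(123, 180, 24, 96)   # ~0.79: slowed aging over dauer days 1-4
#' @export
aging_rate <- function(pba_start_h, pba_end_h, chrono_start_h, chrono_end_h) {
  if (any(chrono_end_h <= chrono_start_h)) {
    stop("chronological span must be positive", call. = FALSE)
  }
  (pba_end_h - pba_start_h) / (chrono_end_h - chrono_start_h)
}

#' Write a clock model to JSON
#'
#' Schema: \code{{"intercept": float, "coefficients": {gene: float},
#' "meta": {...}}}; round-trip stable via [read_clock_model()]. External
#' coefficient tables in the same schema (e.g. a published clock) can be
#' loaded with [read_clock_model()] and used directly in [predict_age()].
#'
#' @param model A \code{clock_model}.
#' @param path Output path.
#' @export
write_clock_model <- function(model, path) {
  stopifnot(inherits(model, "clock_model"))
  jsonlite::write_json(
    list(intercept = model$intercept,
         coefficients = as.list(model$coefficients),
         meta = model$meta),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a clock model from JSON
#'
#' @param path Path to a model JSON written by [write_clock_model()] or an
#'   external coefficient table in the same schema.
#' @return A \code{clock_model}.
#' @export
read_clock_model <- function(path) {
  if (!file.exists(path)) stop("clock model file not found: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$intercept) || is.null(x$coefficients)) {
    stop("clock model JSON must contain 'intercept' and 'coefficients'",
         call. = FALSE)
  }
  cf <- unlist(x$coefficients)
  if (is.null(cf)) cf <- stats::setNames(numeric(0), character(0))
  structure(list(coefficients = cf, intercept = as.numeric(x$intercept),
                 n_genes = length(cf),
                 meta = if (is.null(x$meta)) list() else x$meta),
            class = "clock_model")
}
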