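#' Log10/min-max normalize counts per sample
#'
#' Each sample is log10-transformed after adding one pseudo-count and then
#' min-max normalized into [0, 1]: \code{v = log10(x + 1)};
#' \code{(v - min(v)) / (max(v) - min(v))}.
#'
#' @param counts Non-negative vector (one sample) or gene-by-sample matrix.
#' @return Object of the same shape with values in [0, 1].
#' @examples
#' normalize_sample(c(0, 9, 99))  # 0, 0.5, 1
#' @export
normalize_sample <- function(counts) {
  norm1 <- function(x) {
    if (any(x < 0) || anyNA(x)) stop("counts must be non-negative", call. = FALSE)
    v <- log10(x + 1)
    rng <- range(v)
    if (rng[1] == rng[2]) {
      stop("constant sample: min-max normalization undefined", call. = FALSE)
    }
    (v - rng[1]) / (rng[2] - rng[1])
  }
  if (is.matrix(counts)) {
    out <- apply(counts, 2, norm1)
    dimnames(out) <- dimnames(counts)
    out
  } else {
    norm1(counts)
  }
}

# Binarize normalized values using the original counts to decide which genes
# are "nonzero" for the median threshold (zero-count genes are always 0).
.binarize_normalized <- function(norm, raw) {
  out <- matrix(0L, nrow(norm), ncol(norm), dimnames = dimnames(norm))
  for (j in seq_len(ncol(norm))) {
    nz <- raw[, j] > 0
    if (!any(nz)) {
      stop("sample '", colnames(raw)[j],
           "' has all-zero counts; nonzero median undefined", call. = FALSE)
    }
    thr <- stats::median(norm[nz, j])
    out[, j] <- as.integer(norm[, j] > thr & nz)
  }
  out
}

#' Score samples with a stochastic-data based clock
#'
#' Each sample is normalized ([normalize_sample()]), binarized with the
#' strict-median rule on the normalized nonzero values, and the binarized
#' states of the clock genes are summed, giving a score in
#' \code{[0, length(clock_genes)]} that increases as more clock genes switch
#' on. With \code{sum_mode = "normalized"} the min-max normalized values of
#' the clock genes are summed instead (sensitivity analysis for the
#' alternative reading of the score definition).
#'
#' @param counts Gene-by-sample count matrix.
#' @param model A \code{stochastic_clock_model} from [select_clock_genes()]
#'   (or any list with a \code{clock_genes} character vector).
#' @param sum_mode \code{"binarized"} (default) or \code{"normalized"}.
#' @return data.frame with columns \code{sample_id} and \code{score}.
#' @export
stochastic_score <- function(counts, model,
                             sum_mode = c("binarized", "normalized")) {
  .assert_count_matrix(counts)
  sum_mode <- match.arg(sum_mode)
  genes <- unique(as.character(model$clock_genes))
  if (length(genes) == 0L) stop("model has no clock genes", call. = FALSE)
  present <- genes %in% rownames(counts)
  if (!all(present)) {
    warning(sum(!present), " clock gene(s) absent from counts; ",
            "treated as state 0", call. = FALSE)
  }
  norm <- normalize_sample(counts)
  vals <- if (sum_mode == "binarized") .binarize_normalized(norm, counts) else norm
  score <- colSums(vals[genes[present], , drop = FALSE])
  data.frame(sample_id = colnames(counts), score = unname(score),
             stringsAsFactors = FALSE)
}

#' Select stochastic clock genes from a training time course
#'
#' Candidate genes are those whose binarized state is 0 in the consensus
#' (majority state) of the youngest age group; among candidates, genes are
#' ranked by the slope of their mean binarized state against age (largest
#' positive slope first — the genes most reliably switching on with age) and
#' the top \code{n_genes} are kept. Ties are broken by lexicographic gene id,
#' making selection deterministic.
#'
#' @param training_counts Gene-by-sample count matrix.
#' @param ages Numeric age (hours) per sample column; at least 2 distinct
#'   values.
#' @param n_genes Number of clock genes to select (> 0, at most the number of
#'   candidates).
#' @return Object of class \code{stochastic_clock_model}: list with
#'   \code{clock_genes} (ordered character vector) and \code{meta}.
#' @export
select_clock_genes <- function(training_counts, ages, n_genes) {
  .assert_count_matrix(training_counts, "training_counts")
  if (length(ages) != ncol(training_counts)) {
    stop("ages must have one value per sample column", call. = FALSE)
  }
  if (length(unique(ages)) < 2L) {
    stop("at least 2 distinct age groups required", call. = FALSE)
  }
  if (n_genes <= 0) stop("n_genes must be > 0", call. = FALSE)
  norm <- normalize_sample(training_counts)
  bin <- .binarize_normalized(norm, training_counts)
  young <- ages == min(ages)
  candidate <- rowMeans(bin[, young, drop = FALSE]) < 0.5
  if (sum(candidate) < n_genes) {
    stop("n_genes (", n_genes, ") exceeds the ", sum(candidate),
         " genes with youngest-group consensus state 0", call. = FALSE)
  }
  # OLS slope of mean state vs age, per gene
  age_u <- sort(unique(ages))
  mean_state <- vapply(age_u, function(a) {
    rowMeans(bin[, ages == a, drop = FALSE])
  }, numeric(nrow(bin)))
  tc <- age_u - mean(age_u)
  slope <- drop(mean_state %*% tc) / sum(tc^2)
  ord <- order(-slope, rownames(bin))
  ord <- ord[candidate[ord]]
  structure(list(
    clock_genes = rownames(bin)[ord[seq_len(n_genes)]],
    meta = list(n_genes = as.integer(n_genes),
                n_candidates = sum(candidate),
                ages = age_u)
  ), class = "stochastic_clock_model")
}

#' Write a stochastic clock model to JSON
#' @param model A \code{stochastic_clock_model}.
#' @param path Output path.
#' @export
write_stochastic_model <- function(model, path) {
  jsonlite::write_json(list(clock_genes = model$clock_genes, meta = model$meta),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a stochastic clock model from JSON
#' @param path Path to a model JSON.
#' @return A \code{stochastic_clock_model}.
#' @export
read_stochastic_model <- function(path) {
  if (!file.exists(path)) {
    stop("stochastic model file not found: ", path, call. = FALSE)
  }
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$clock_genes) || length(x$clock_genes) == 0L) {
    stop("stochastic model JSON must contain non-empty 'clock_genes'",
         call. = FALSE)
  }
  structure(list(clock_genes = as.character(x$clock_genes),
                 meta = if (is.null(x$meta)) list() else x$meta),
            class = "stochastic_clock_model")
}
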