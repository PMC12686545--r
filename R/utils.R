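#' @keywords internal
"_PACKAGE"

# Shared argument checks. All user-facing errors go through stop(call. = FALSE)
# so messages read as contract violations, not tracebacks.

.assert_count_matrix <- function(counts, arg = "counts") {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop(sprintf("'%s' must be a numeric gene-by-sample matrix", arg), call. = FALSE)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop(sprintf("'%s' must have gene rownames and sample colnames", arg), call. = FALSE)
  }
  if (any(counts < 0) || anyNA(counts)) {
    stop(sprintf("'%s' must be non-negative with no missing values", arg), call. = FALSE)
  }
  invisible(counts)
}

.assert_scalar_number <- function(x, arg) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", arg), call. = FALSE)
  }
  invisible(x)
}

# geometric mean rescaling used for size-factor identifiability
.geomean <- function(x) exp(mean(log(x)))
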