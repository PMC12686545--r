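#' Prefilter low-count genes
#'
#' Retains genes with counts of at least \code{min_count} in at least
#' \code{min_samples} samples (the smallest group size in the motivating
#' design), the standard pre-filter before differential expression.
#'
#' @param counts Gene-by-sample count matrix.
#' @param min_count Minimum count (default 10).
#' @param min_samples Minimum number of samples reaching it (default 3).
#' @return The retained rows of \code{counts}.
#' @export
prefilter <- function(counts, min_count = 10, min_samples = 3) {
  .assert_count_matrix(counts)
  keep <- rowSums(counts >= min_count) >= min_samples
  if (!any(keep)) warning("prefilter removed every gene", call. = FALSE)
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size-factor normalization
#'
#' Computes per-sample size factors as the median, over genes expressed in
#' every sample, of the ratio of the gene's count to its geometric mean
#' across samples; factors are rescaled to geometric mean 1 for
#' identifiability and counts are divided by them.
#'
#' @param counts Gene-by-sample count matrix.
#' @return List with \code{normalized} (numeric matrix) and
#'   \code{size_factors} (named per-sample vector, geometric mean 1).
#' @export
normalize_counts <- function(counts) {
  .assert_count_matrix(counts)
  all_pos <- rowSums(counts == 0) == 0
  if (!any(all_pos)) {
    stop("no gene has nonzero counts in all samples; size factors undefined",
         call. = FALSE)
  }
  logc <- log(counts[all_pos, , drop = FALSE])
  logmeans <- rowMeans(logc)
  sf <- apply(logc, 2, function(col) exp(stats::median(col - logmeans)))
  sf <- sf / .geomean(sf)
  list(normalized = sweep(counts, 2, sf, "/"),
       size_factors = stats::setNames(sf, colnames(counts)))
}

#' Per-gene linear trend test on log-normalized counts
#'
#' For each gene, ordinary least squares of \code{log2(normalized +
#' pseudocount)} on the continuous time covariate (dauer day or exit hour).
#' The slope is the log2 fold change per unit time; significance is a t-test
#' on the slope with Benjamini-Hochberg adjustment across genes, and the
#' direction calls a gene up (down) when \code{q <= alpha} with a positive
#' (negative) slope.
#'
#' @param norm_counts Normalized gene-by-sample matrix (see
#'   [normalize_counts()]).
#' @param times Numeric covariate per sample column, in the unit the slope
#'   should be expressed in; at least 3 distinct values.
#' @param alpha BH-adjusted significance cutoff for the direction call
#'   (default 0.05).
#' @param pseudocount Offset added before the log2 transform (default 0.5).
#' @return data.frame with columns \code{gene_id}, \code{slope} (log2 per
#'   time unit), \code{se}, \code{stat}, \code{p}, \code{q}, \code{direction}
#'   (\code{"up"}, \code{"down"} or \code{"ns"}).
#' @export
trend_test <- function(norm_counts, times, alpha = 0.05, pseudocount = 0.5) {
  if (!is.matrix(norm_counts) || !is.numeric(norm_counts)) {
    stop("'norm_counts' must be a numeric matrix", call. = FALSE)
  }
  if (length(times) != ncol(norm_counts)) {
    stop("times must have one value per sample column", call. = FALSE)
  }
  if (length(unique(times)) < 3L) {
    stop("at least 3 distinct time values required", call. = FALSE)
  }
  .ols_trend(norm_counts, times, alpha, pseudocount)
}

# Shared per-gene OLS on log2(normalized + pseudocount); slope t-test with
# BH adjustment. Used by trend_test (continuous time) and de_two_group
# (0/1 indicator, where the slope is the log2 fold change).
.ols_trend <- function(norm_counts, x, alpha, pseudocount) {
  n <- ncol(norm_counts)
  y <- log2(norm_counts + pseudocount)
  tc <- x - mean(x)
  sxx <- sum(tc^2)
  slope <- drop(y %*% tc) / sxx
  yc <- y - rowMeans(y)
  resid <- yc - outer(slope, tc)
  rss <- rowSums(resid^2)
  df <- n - 2L
  se <- sqrt(rss / df / sxx)
  stat <- ifelse(se > 0, slope / se, ifelse(slope == 0, 0, Inf * sign(slope)))
  p <- 2 * stats::pt(-abs(stat), df)
  q <- stats::p.adjust(p, method = "BH")
  direction <- ifelse(q <= alpha & slope > 0, "up",
                      ifelse(q <= alpha & slope < 0, "down", "ns"))
  data.frame(gene_id = rownames(norm_counts), slope = slope, se = se,
             stat = stat, p = p, q = q, direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-group differential expression on log-normalized counts
#'
#' Per-gene OLS of \code{log2(normalized + pseudocount)} on a 0/1 group
#' indicator — equivalent to a pooled-variance t-test — so the slope is the
#' log2 fold change of group 1 over group 0. Used for the UV-treated versus
#' untreated comparison feeding the GLTD test.
#'
#' @param norm_counts Normalized gene-by-sample matrix.
#' @param group Vector with exactly two levels, one per sample column; the
#'   higher level (after conversion to 0/1 by first occurrence order of the
#'   sorted unique values) is the "treated" group.
#' @param alpha BH cutoff for the direction call (default 0.05).
#' @param pseudocount Offset before the log2 transform (default 0.5).
#' @return data.frame as [trend_test()], slope in log2 fold-change units.
#' @export
de_two_group <- function(norm_counts, group, alpha = 0.05, pseudocount = 0.5) {
  if (length(group) != ncol(norm_counts)) {
    stop("group must have one value per sample column", call. = FALSE)
  }
  lev <- sort(unique(group))
  if (length(lev) != 2L) stop("group must have exactly 2 levels", call. = FALSE)
  .ols_trend(norm_counts, as.numeric(group == lev[2]), alpha, pseudocount)
}

#' Cluster gene expression trajectories with k-means and elbow selection
#'
#' Per-gene profiles are the replicate means at each timepoint, z-scaled per
#' gene; genes with zero variance across timepoints are excluded with a
#' warning. k-means (with \code{n_init} random restarts and up to
#' \code{max_iter} iterations, matching the clustering settings used for the
#' dauer aging trajectories) is run for every k in \code{k_range}, the
#' within-cluster sum of squares (WCSS) is recorded, and the elbow is made
#' explicit as the interior k maximizing the second difference of the WCSS
#' curve.
#'
#' @param norm_counts Normalized gene-by-sample matrix.
#' @param times Timepoint per sample column.
#' @param k_range Integer vector of cluster counts to scan (default 1:10).
#' @param seed Seed; clustering is deterministic given it.
#' @param n_init Number of k-means restarts (default 100).
#' @param max_iter Maximum k-means iterations (default 1000).
#' @return Object of class \code{cluster_profiles}: list with
#'   \code{clusters} (data.frame gene_id, cluster at the selected k),
#'   \code{k_selected}, \code{wcss} (data.frame k, wcss), \code{centers}
#'   (cluster-by-timepoint means at the selected k) and
#'   \code{assignments_by_k}.
#' @export
cluster_profiles <- function(norm_counts, times, k_range = 1:10, seed = 1L,
                             n_init = 100L, max_iter = 1000L) {
  if (!is.matrix(norm_counts)) stop("'norm_counts' must be a matrix", call. = FALSE)
  if (length(times) != ncol(norm_counts)) {
    stop("times must have one value per sample column", call. = FALSE)
  }
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 1L)) stop("k_range must be positive", call. = FALSE)
  tp <- sort(unique(times))
  prof <- vapply(tp, function(a) {
    rowMeans(norm_counts[, times == a, drop = FALSE])
  }, numeric(nrow(norm_counts)))
  sds <- apply(prof, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " gene(s) with zero variance across timepoints ",
            "excluded from clustering", call. = FALSE)
    prof <- prof[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  prof <- (prof - rowMeans(prof)) / sds
  if (nrow(prof) < max(k_range)) {
    stop("fewer genes (", nrow(prof), ") than max k (", max(k_range), ")",
         call. = FALSE)
  }
  fits <- lapply(k_range, function(k) {
    set.seed(seed + k)
    stats::kmeans(prof, centers = k, nstart = n_init, iter.max = max_iter)
  })
  wcss <- vapply(fits, function(f) f$tot.withinss, numeric(1))
  if (length(k_range) >= 3L) {
    d2 <- diff(wcss, differences = 2)  # wcss[i-1] - 2*wcss[i] + wcss[i+1]
    k_selected <- k_range[which.max(d2) + 1L]
  } else {
    k_selected <- max(k_range)
    warning("k_range too short for elbow selection; using k = ", k_selected,
            call. = FALSE)
  }
  sel <- fits[[match(k_selected, k_range)]]
  structure(list(
    clusters = data.frame(gene_id = rownames(prof),
                          cluster = unname(sel$cluster),
                          row.names = NULL, stringsAsFactors = FALSE),
    k_selected = k_selected,
    wcss = data.frame(k = k_range, wcss = wcss),
    centers = sel$centers,
    timepoints = tp,
    assignments_by_k = stats::setNames(
      lapply(fits, function(f) stats::setNames(unname(f$cluster), rownames(prof))),
      paste0("k", k_range))
  ), class = "cluster_profiles")
}

#' Direction concordance between signed DEG sets
#'
#' For each pair of differentially-expressed-gene sets, counts the shared
#' genes and the fraction of shared genes regulated in the same direction.
#' The fraction is NA when two sets share no genes.
#'
#' @param deg_sets Named list; each element is either a data.frame with
#'   columns \code{gene_id} and \code{direction} (\code{"up"}/\code{"down"})
#'   or a named numeric vector of signs.
#' @return Object of class \code{overlap_matrix}: list with symmetric
#'   matrices \code{n_shared} and \code{frac_same_direction}, plus a tidy
#'   \code{pairs} data.frame (set_a, set_b, n_shared, frac_same_direction).
#' @export
exit_overlap <- function(deg_sets) {
  if (is.null(names(deg_sets)) || any(!nzchar(names(deg_sets)))) {
    stop("deg_sets must be a named list", call. = FALSE)
  }
  signs <- lapply(deg_sets, function(s) {
    if (is.data.frame(s)) {
      stats::setNames(ifelse(s$direction == "up", 1, -1), s$gene_id)
    } else {
      stats::setNames(sign(as.numeric(s)), names(s))
    }
  })
  nm <- names(signs)
  k <- length(nm)
  n_shared <- matrix(0L, k, k, dimnames = list(nm, nm))
  frac <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      shared <- intersect(names(signs[[i]]), names(signs[[j]]))
      n_shared[i, j] <- length(shared)
      if (length(shared) > 0) {
        frac[i, j] <- mean(signs[[i]][shared] == signs[[j]][shared])
      }
    }
  }
  pairs <- do.call(rbind, lapply(seq_len(k - 1), function(i) {
    do.call(rbind, lapply(seq(i + 1, k), function(j) {
      data.frame(set_a = nm[i], set_b = nm[j], n_shared = n_shared[i, j],
                 frac_same_direction = frac[i, j], stringsAsFactors = FALSE)
    }))
  }))
  structure(list(n_shared = n_shared, frac_same_direction = frac,
                 pairs = pairs),
            class = "overlap_matrix")
}

#' PCA embedding of log-normalized samples
#'
#' PCA on \code{log2(normalized + pseudocount)}, gene-centered. Orientation
#' is made reproducible by forcing the largest-magnitude loading of each
#' component positive. Loadings are returned so they can be exported for
#' external enrichment tools.
#'
#' @param norm_counts Normalized gene-by-sample matrix.
#' @param n_components Number of components (truncated with a warning when it
#'   exceeds what the data support).
#' @param pseudocount Offset before the log2 transform (default 0.5).
#' @return List with \code{scores} (samples x components),
#'   \code{loadings} (genes x components) and \code{var_explained}
#'   (fractions of total variance; sums to <= 1 over the returned
#'   components).
#' @export
pca_embed <- function(norm_counts, n_components = 2L, pseudocount = 0.5) {
  if (!is.matrix(norm_counts)) stop("'norm_counts' must be a matrix", call. = FALSE)
  if (ncol(norm_counts) < 2L) stop("at least 2 samples required", call. = FALSE)
  y <- t(log2(norm_counts + pseudocount))
  pc <- stats::prcomp(y, center = TRUE, scale. = FALSE)
  avail <- ncol(pc$rotation)
  if (n_components > avail) {
    warning("only ", avail, " components available; truncating", call. = FALSE)
    n_components <- avail
  }
  idx <- seq_len(n_components)
  rot <- pc$rotation[, idx, drop = FALSE]
  sco <- pc$x[, idx, drop = FALSE]
  for (j in idx) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  list(scores = sco, loadings = rot,
       var_explained = (pc$sdev^2 / sum(pc$sdev^2))[idx])
}
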