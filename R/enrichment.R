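#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields \code{name},
#' \code{description}, then member gene ids. Duplicate member ids within a
#' set are deduplicated; duplicate set names or lines with fewer than 3
#' fields are errors.
#'
#' @param path Path to a GMT file.
#' @return Object of class \code{gene_set_collection}: list with \code{sets}
#'   (named list of character vectors) and \code{description} (named
#'   character).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    stop("malformed GMT line ", bad[1], " in ", path,
         ": fewer than 3 tab-separated fields", call. = FALSE)
  }
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate gene set name(s) in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  if (any(lengths(sets) == 0L)) {
    stop("empty gene set(s) in ", path, call. = FALSE)
  }
  descr <- stats::setNames(vapply(fields, `[[`, character(1), 2L), nm)
  structure(list(sets = sets, description = descr),
            class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#'
#' @param collection A \code{gene_set_collection}.
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$description[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' One-sided (upper tail) hypergeometric test of each gene set against a
#' query list within a universe: with universe size N, set size within the
#' universe m, query size n and overlap k, the p-value is the probability of
#' drawing at least k set members in n draws without replacement,
#' \code{P(X >= k)}. P-values are BH-adjusted across the tested sets. The
#' gene ratio k/n and rich factor k/m are reported for bubble-plot style
#' summaries.
#'
#' @param query_genes Character vector of query gene ids (e.g. significant
#'   genes); ids outside the universe are dropped with a warning.
#' @param sets A \code{gene_set_collection}.
#' @param universe Character vector of background gene ids (e.g. all genes
#'   passing [prefilter()]).
#' @param min_set_size Sets with fewer members within the universe are
#'   skipped (default 3); sets with zero members are skipped with a warning.
#' @param cutoff BH-adjusted significance cutoff for the \code{significant}
#'   flag (default 0.05).
#' @return data.frame sorted by p with columns \code{set}, \code{k},
#'   \code{m}, \code{n}, \code{N}, \code{p}, \code{q}, \code{gene_ratio},
#'   \code{rich_factor}, \code{significant}.
#' @export
ora <- function(query_genes, sets, universe, min_set_size = 3L,
                cutoff = 0.05) {
  stopifnot(inherits(sets, "gene_set_collection"))
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("universe is empty", call. = FALSE)
  query <- unique(as.character(query_genes))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped",
            call. = FALSE)
    query <- intersect(query, universe)
  }
  N <- length(universe)
  n <- length(query)
  members <- lapply(sets$sets, intersect, y = universe)
  empty <- lengths(members) == 0L
  if (any(empty)) {
    warning(sum(empty), " gene set(s) with no members in the universe skipped",
            call. = FALSE)
  }
  keep <- lengths(members) >= max(1L, min_set_size) & !empty
  members <- members[keep]
  if (length(members) == 0L) {
    return(data.frame(set = character(), k = integer(), m = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      q = numeric(), gene_ratio = numeric(),
                      rich_factor = numeric(), significant = logical()))
  }
  m <- lengths(members)
  k <- vapply(members, function(s) length(intersect(s, query)), integer(1))
  p <- stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(set = names(members), k = k, m = m, n = n, N = N,
                    p = p, q = q,
                    gene_ratio = if (n > 0) k / n else NA_real_,
                    rich_factor = k / m,
                    significant = q <= cutoff,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p, out$set), , drop = FALSE]
}
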