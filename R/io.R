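#' Read a gene-by-sample count matrix from TSV
#'
#' The expected layout is the one the simulator writes: a header line, a first
#' column of gene identifiers (named \code{gene_id}) and one integer column per
#' sample.
#'
#' @param path Path to a tab-separated counts file.
#' @return Integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  .assert_count_matrix(m)
}

#' Write a count matrix to TSV
#'
#' @param counts Gene-by-sample matrix.
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  .assert_count_matrix(counts)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Requires columns \code{sample_id}, \code{group}, \code{timepoint_h} and
#' \code{median_lifespan_h} (the latter may be NA for cohorts without lifespan
#' data).
#'
#' @param path Path to a tab-separated metadata file.
#' @return data.frame of per-sample metadata.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path, call. = FALSE)
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "timepoint_h", "median_lifespan_h")
  miss <- setdiff(need, names(md))
  if (length(miss)) {
    stop("metadata file ", path, " lacks required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  md$timepoint_h <- as.numeric(md$timepoint_h)
  md$median_lifespan_h <- as.numeric(md$median_lifespan_h)
  md
}

#' Write a data.frame as TSV
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene list (one identifier per line)
#'
#' @param path Path to a plain-text gene list.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list not found: ", path, call. = FALSE)
  x <- readLines(path)
  x <- trimws(x)
  unique(x[nzchar(x)])
}
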