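#' Write a taxon-by-sample count table as TSV
#'
#' First column `taxon`, one column per sample, header row, integer (or
#' real, after normalization) cells.
#'
#' @param counts taxa x samples matrix with dimnames.
#' @param path Output path.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(taxon = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxon-by-sample count table from TSV
#'
#' @param path TSV written by [write_counts_tsv()] (first column = taxon).
#' @return taxa x samples numeric matrix.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write/read a plain data.frame as TSV
#'
#' @param df A data.frame.
#' @param path Output path.
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a distance matrix as square TSV with a metric tag
#'
#' The metric tag is stored on a leading `# metric:` comment line and
#' round-trips through [read_dist_tsv()].
#'
#' @param d A `dist` object (with optional `metric` attribute) or square
#'   matrix.
#' @param path Output path.
#' @export
write_dist_tsv <- function(d, path) {
  metric <- attr(d, "metric")
  m <- as.matrix(d)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(metric)) writeLines(paste0("# metric: ", metric), con)
  utils::write.table(data.frame(sample = rownames(m), m, check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dist_tsv
#' @export
read_dist_tsv <- function(path) {
  first <- readLines(path, n = 1)
  metric <- NULL
  skip <- 0
  if (startsWith(first, "# metric:")) {
    metric <- trimws(sub("# metric:", "", first, fixed = TRUE))
    skip <- 1
  }
  df <- utils::read.delim(path, skip = skip, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  d <- stats::as.dist(m)
  attr(d, "metric") <- metric
  d
}
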