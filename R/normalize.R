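#' Genome-size normalization
#'
#' Larger genomes attract more shotgun reads at equal cell abundance, so
#' read counts are divided by the genome size of the assigned taxon:
#' strain-level sizes are used where available, otherwise the species-level
#' size (the mean over published strains of that species).
#'
#' @param counts taxa x samples matrix.
#' @param sizes Data.frame with columns `taxon`, `size_bp` and optionally
#'   `level` (`"strain"`/`"species"`; strain rows take precedence when a
#'   taxon appears at both levels).
#' @return Real-valued matrix of size-normalized abundances (reads/bp).
#' @export
genome_size_normalize <- function(counts, sizes) {
  stopifnot(all(c("taxon", "size_bp") %in% names(sizes)))
  if (any(sizes$size_bp <= 0)) stop("genome sizes must be positive")
  if (!is.null(sizes$level)) {
    sizes <- sizes[order(match(sizes$level, c("strain", "species"))), ]
    sizes <- sizes[!duplicated(sizes$taxon), ]
  }
  idx <- match(rownames(counts), sizes$taxon)
  if (anyNA(idx))
    stop("missing genome size for taxa: ",
         paste(rownames(counts)[is.na(idx)], collapse = ", "))
  counts / sizes$size_bp[idx]
}

#' Total sum scaling (TSS)
#'
#' Converts each sample to per-sample proportions (columns sum to 1).
#'
#' @param counts taxa x samples matrix with positive column sums.
#' @return Matrix of proportions.
#' @export
tss_normalize <- function(counts) {
  cs <- colSums(counts)
  if (any(cs <= 0)) stop("empty sample(s): ",
                         paste(colnames(counts)[cs <= 0], collapse = ", "))
  sweep(counts, 2, cs, "/")
}

#' Cumulative sum scaling (CSS)
#'
#' Quantile-based scaling robust to a few dominant taxa: each sample's
#' scale factor is the sum of its counts at or below the sample's `p`-th
#' quantile of *nonzero* counts; cells are divided by the factor and
#' rescaled by the median factor so values stay on a count-like scale.
#'
#' @param counts taxa x samples integer matrix.
#' @param p Quantile (default 0.5).
#' @return List: `counts` (normalized matrix), `factors` (per-sample scale
#'   factors).
#' @export
css_normalize <- function(counts, p = 0.5) {
  if (any(colSums(counts > 0) == 0))
    stop("sample(s) with no nonzero counts: ",
         paste(colnames(counts)[colSums(counts > 0) == 0], collapse = ", "))
  sf <- apply(counts, 2, function(x) {
    nz <- x[x > 0]
    q <- stats::quantile(nz, p, names = FALSE)
    sum(x[x <= q])
  })
  med <- stats::median(sf)
  out <- sweep(counts, 2, sf, "/") * med
  list(counts = out, factors = sf)
}
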