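#' Community dissimilarity between samples
#'
#' Abundance-based Bray-Curtis or presence/absence-based binary Jaccard
#' distances between sample columns (computed with \pkg{vegan}).
#'
#' @param counts taxa x samples matrix (raw or normalized).
#' @param metric `"bray_curtis"` or `"jaccard_binary"`.
#' @return A `dist` object with a `metric` attribute; distances lie in
#'   `[0, 1]` (pairs of all-zero samples give `NA`).
#' @export
community_distance <- function(counts, metric = c("bray_curtis", "jaccard_binary")) {
  metric <- match.arg(metric)
  if (ncol(counts) < 2) stop("need at least 2 samples")
  d <- switch(metric,
    bray_curtis = suppressWarnings(vegan::vegdist(t(counts), method = "bray")),
    jaccard_binary = suppressWarnings(
      vegan::vegdist(t(counts), method = "jaccard", binary = TRUE)))
  attr(d, "metric") <- metric
  d
}

#' Principal coordinate analysis (PCoA)
#'
#' Classical metric scaling: Gower double-centering of the squared
#' distance matrix followed by eigendecomposition. Negative eigenvalues
#' (possible for semi-metric dissimilarities such as Bray-Curtis) are
#' reported; the proportion of variation uses the sum of positive
#' eigenvalues as denominator. A Cailliez additive correction is available
#' by flag.
#'
#' @param d A `dist` object or square symmetric matrix.
#' @param correction `"none"` (default) or `"cailliez"`.
#' @return Object of class `pcoa_result`: `eigenvalues` (descending,
#'   including negatives), `coordinates` (samples x retained axes, one per
#'   positive eigenvalue), `prop_explained`, `negative_eigenvalues`.
#' @export
pcoa <- function(d, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  d <- stats::as.dist(d)
  if (anyNA(d)) stop("distance matrix contains NA")
  n <- attr(d, "Size")
  fit <- suppressWarnings(
    stats::cmdscale(d, k = n - 1, eig = TRUE, add = correction == "cailliez"))
  eig <- fit$eig
  tol <- sqrt(.Machine$double.eps) * max(abs(eig))
  pos <- eig > tol
  coords <- fit$points[, seq_len(sum(pos)), drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  structure(list(
    eigenvalues = eig,
    coordinates = coords,
    prop_explained = eig[pos] / sum(eig[pos]),
    negative_eigenvalues = eig[eig < -tol],
    correction = correction
  ), class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  k <- min(4, length(x$prop_explained))
  cat(sprintf("PCoA: %d samples, %d positive axes\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  cat("  variation explained:",
      paste(sprintf("%s %.1f%%", colnames(x$coordinates)[seq_len(k)],
                    100 * x$prop_explained[seq_len(k)]), collapse = ", "), "\n")
  if (length(x$negative_eigenvalues))
    cat(sprintf("  %d negative eigenvalues (min %.3g)\n",
                length(x$negative_eigenvalues), min(x$negative_eigenvalues)))
  invisible(x)
}

#' Taxon loadings on ordination axes
#'
#' Weighted-average species scores: the loading of a taxon on an axis is
#' the abundance-weighted mean of the axis scores of the samples carrying
#' it, computed on TSS-normalized input. Taxa absent everywhere get `NA`.
#'
#' @param ord A [pcoa()] result.
#' @param counts taxa x samples matrix on the same samples.
#' @param n_axes Number of axes to compute loadings for.
#' @return taxa x axes matrix of loadings.
#' @export
taxon_loadings <- function(ord, counts, n_axes = 2) {
  scores <- ord$coordinates
  if (!all(rownames(scores) %in% colnames(counts)))
    stop("ordination samples not all present in the count table")
  counts <- counts[, rownames(scores), drop = FALSE]
  n_axes <- min(n_axes, ncol(scores))
  w <- tss_normalize(counts)
  tot <- rowSums(w)
  L <- (w %*% scores[, seq_len(n_axes), drop = FALSE]) / tot
  L[tot == 0, ] <- NA
  L
}

#' Driving taxa of an ordination
#'
#' The taxa with the largest absolute loadings on the first `n_axes` PCoA
#' axes (`top_k` per axis, default four on each of the first two axes),
#' returned as a unique list preserving first-seen order — up to
#' `n_axes * top_k` taxa when no taxon dominates both axes. Ties break by
#' (absolute loading descending, label ascending).
#'
#' @param loadings taxa x axes loading matrix from [taxon_loadings()].
#' @param n_axes Axes to consider.
#' @param top_k Taxa per axis.
#' @return Character vector of driving-taxon labels.
#' @export
driving_taxa <- function(loadings, n_axes = 2, top_k = 4) {
  n_axes <- min(n_axes, ncol(loadings))
  labs <- rownames(loadings)
  if (length(labs) < top_k) {
    warning("fewer taxa than top_k; returning all")
    return(labs)
  }
  picked <- character(0)
  for (a in seq_len(n_axes)) {
    l <- abs(loadings[, a])
    ok <- !is.na(l)
    ord <- order(-l[ok], labs[ok])
    picked <- c(picked, labs[ok][ord][seq_len(min(top_k, sum(ok)))])
  }
  unique(picked)
}
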