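#' Library-size frequency test for reagent contaminants
#'
#' Contaminants introduced at a roughly constant absolute amount per
#' library make up a *larger share* of low-input samples, so their relative
#' abundance is negatively correlated with total sequencing depth. For each
#' taxon this test correlates the taxon's proportion of the total read
#' count (including host DNA, i.e. `total_reads` from the metadata) with
#' that total read count across samples, adjusts two-sided p-values by
#' Benjamini-Hochberg, and flags taxa with a significant negative
#' correlation.
#'
#' @param counts taxa x samples integer matrix.
#' @param metadata Data.frame with `sample` and `total_reads` columns
#'   covering every sample in `counts`.
#' @param alpha FDR level for flagging.
#' @param method Correlation kind: `"spearman"` (default; robust to
#'   heavy-tailed proportions) or `"pearson"`.
#'
#' @return Data.frame of class `freq_test`: taxon, statistic (correlation
#'   coefficient), p, q, flagged. Constant taxa get `NA` statistic and
#'   `q = 1`.
#' @export
taxon_frequency_test <- function(counts, metadata, alpha = 0.05,
                                 method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (ncol(counts) < 4) stop("insufficient data: need at least 4 samples")
  idx <- match(colnames(counts), metadata$sample)
  if (anyNA(idx)) stop("metadata missing samples: ",
                       paste(colnames(counts)[is.na(idx)], collapse = ", "))
  total <- metadata$total_reads[idx]
  if (any(total <= 0)) stop("total_reads must be positive")
  prop <- sweep(counts, 2, total, "/")

  stat <- p <- rep(NA_real_, nrow(counts))
  for (j in seq_len(nrow(counts))) {
    x <- prop[j, ]
    if (stats::sd(x) == 0) next
    ct <- suppressWarnings(
      stats::cor.test(x, total, method = method, exact = FALSE))
    stat[j] <- unname(ct$estimate)
    p[j] <- ct$p.value
  }
  q <- rep(1, nrow(counts))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  res <- data.frame(taxon = rownames(counts), statistic = stat, p = p, q = q,
                    flagged = !is.na(stat) & stat < 0 & q < alpha,
                    stringsAsFactors = FALSE)
  attr(res, "alpha") <- alpha
  attr(res, "method") <- method
  class(res) <- c("freq_test", "data.frame")
  res
}

#' @export
print.freq_test <- function(x, ...) {
  cat(sprintf("Library-size frequency test (%s, BH alpha = %g)\n",
              attr(x, "method"), attr(x, "alpha")))
  cat(sprintf("  %d taxa tested, %d flagged as candidate contaminants\n",
              nrow(x), sum(x$flagged)))
  if (any(x$flagged)) {
    top <- x[x$flagged, ][order(x[x$flagged, "q"]), ]
    print(utils::head(`class<-`(top, "data.frame"), 10), row.names = FALSE)
  }
  invisible(x)
}
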