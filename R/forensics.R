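#' Summarize percent-identity of reads/contigs to a reference genome
#'
#' Human or laboratory contaminants are expected to match human-derived
#' reference genomes at (close to) 100% identity, whereas genuinely
#' host-associated relatives are more divergent. This tallies how many
#' identity values equal 100 and how many reach each threshold.
#'
#' @param identities Percent identities in `[0, 100]`.
#' @param thresholds Identity thresholds (percent) for the `>=` counts.
#' @return List: `n`, `eq100`, `ge` (named counts per threshold),
#'   `frac_eq100`, `frac_ge`.
#' @export
identity_summary <- function(identities, thresholds = c(97)) {
  if (length(identities) && (any(identities < 0) || any(identities > 100)))
    stop("identities must be within [0, 100]")
  n <- length(identities)
  eq100 <- sum(identities == 100)
  ge <- vapply(thresholds, function(t) sum(identities >= t), numeric(1))
  names(ge) <- paste0("ge", thresholds)
  list(n = n, eq100 = eq100, ge = ge,
       frac_eq100 = if (n > 0) eq100 / n else 0,
       frac_ge = if (n > 0) ge / n else ge * 0)
}

#' Between-lane consistency of a taxon's relative abundance
#'
#' Samples pooled and sequenced across multiple lanes should yield nearly
#' identical relative abundances per lane if a taxon entered the library
#' before sequencing; lane-specific contamination shows up as a high
#' coefficient of variation. Computes CV = sd/mean of per-lane relative
#' abundances within each sample and aggregates across samples.
#'
#' @param lane_abund lanes x samples matrix of the taxon's relative
#'   abundance (or counts) per lane.
#' @param aggregate How to summarize per-sample CVs: `"mean"` (default) or
#'   `"median"`.
#' @return List: `cv` (aggregate), `per_sample` (CV per sample; `NA` where
#'   the lane mean is 0).
#' @export
lane_consistency_cv <- function(lane_abund, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  lane_abund <- as.matrix(lane_abund)
  if (nrow(lane_abund) < 2) stop("need at least 2 lanes")
  per <- apply(lane_abund, 2, function(v) {
    mu <- mean(v)
    if (mu == 0) NA_real_ else stats::sd(v) / mu
  })
  agg <- if (aggregate == "mean") mean(per, na.rm = TRUE) else
    stats::median(per, na.rm = TRUE)
  list(cv = agg, per_sample = per)
}
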