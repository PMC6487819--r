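#' Merge reads with identical sequences
#'
#' Collapses a FASTA/FASTQ read set to one representative per distinct
#' sequence string (exact match after case normalization), the
#' deduplication step used to remove PCR duplicates generated during
#' library indexing. The first-seen record is kept as representative.
#'
#' @param input Path to a FASTA or FASTQ file, or a character vector of
#'   sequences.
#' @param output Optional path; deduplicated reads are written as FASTA.
#' @param format `"auto"` (by extension), `"fasta"` or `"fastq"`.
#'
#' @return List: `sequences` (deduplicated, first-seen order), `n_in`,
#'   `n_out`, `copies` (per representative multiplicity), `output`.
#' @export
merge_identical_reads <- function(input, output = NULL, format = "auto") {
  if (is.character(input) && length(input) == 1 && file.exists(input)) {
    if (format == "auto") {
      format <- if (grepl("\\.f(ast)?q(\\.gz)?$", input, ignore.case = TRUE))
        "fastq" else "fasta"
    }
    seqs <- tryCatch(
      as.character(Biostrings::readDNAStringSet(input, format = format)),
      error = function(e) stop("parse error reading ", input, ": ",
                               conditionMessage(e), call. = FALSE))
  } else {
    seqs <- as.character(input)
  }
  seqs <- toupper(seqs)
  n_in <- length(seqs)
  if (n_in == 0) {
    if (!is.null(output)) Biostrings::writeXStringSet(Biostrings::DNAStringSet(), output)
    return(list(sequences = character(0), n_in = 0L, n_out = 0L,
                copies = integer(0), output = output))
  }
  keep <- !duplicated(seqs)
  uniq <- seqs[keep]
  copies <- as.integer(table(factor(seqs, levels = uniq)))
  if (!is.null(output)) {
    x <- Biostrings::DNAStringSet(uniq)
    names(x) <- sprintf("read_%06d", seq_along(uniq))
    Biostrings::writeXStringSet(x, output)
  }
  list(sequences = uniq, n_in = n_in, n_out = length(uniq),
       copies = copies, output = output)
}

#' Minimum-read taxon filter
#'
#' Zeroes any taxon-sample cell supported by fewer than `min_reads`
#' aligned reads (the per-sample detection threshold applied at taxonomic
#' assignment), then drops taxa left with all-zero rows.
#'
#' @param counts taxa x samples integer matrix.
#' @param min_reads Detection threshold (default 5 reads).
#' @return Filtered count matrix.
#' @export
filter_min_reads <- function(counts, min_reads = 5L) {
  if (any(counts < 0)) stop("negative counts are not allowed")
  out <- counts
  out[out < min_reads] <- 0L
  out[rowSums(out) > 0, , drop = FALSE]
}

#' Depth subsampling without replacement
#'
#' For each sample and fraction, draws `round(fraction * depth)` reads
#' without replacement from that sample's reads (a multivariate
#' hypergeometric draw over taxa, realized by a sequential hypergeometric
#' chain), emulating re-sequencing the same library at lower depth.
#'
#' @param counts taxa x samples integer matrix.
#' @param fractions Vector of fractions in (0, 1].
#' @param seed RNG seed.
#' @return Named list (one element per fraction) of count matrices.
#' @export
downsample_counts <- function(counts, fractions, seed = NULL) {
  if (any(fractions <= 0 | fractions > 1)) stop("fractions must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(fractions, function(f) {
    sub <- counts
    for (s in seq_len(ncol(counts))) {
      sub[, s] <- rmvhyper1(counts[, s], round(f * sum(counts[, s])))
    }
    storage.mode(sub) <- "integer"
    sub
  })
  names(out) <- as.character(fractions)
  out
}

## one multivariate hypergeometric draw: k balls from urn with counts x
rmvhyper1 <- function(x, k) {
  n <- length(x)
  out <- integer(n)
  remaining <- sum(x)
  left <- k
  for (j in seq_len(n)) {
    if (left <= 0) break
    remaining <- remaining - x[j]
    if (remaining <= 0) { out[j] <- left; break }
    out[j] <- stats::rhyper(1, m = x[j], n = remaining, k = left)
    left <- left - out[j]
  }
  out
}

#' Coverage-evenness flag for a mapped genome
#'
#' Computes per-window read coverage along a genome from read start
#' positions and flags profiles showing read stacking (a window with
#' coverage far above the genome mean) and/or large unmapped gaps (an
#' excess of zero-coverage windows) — the signature of spurious taxon
#' assignments supported by a few repetitive regions.
#'
#' Thresholds are exposed configuration; the defaults (window 1 kb,
#' `stack_fold = 10`, `gap_frac = 0.5`) are calibrated so Poisson-uniform
#' read placement at modest coverage is rarely flagged.
#'
#' @param genome_length Genome length (bp).
#' @param read_starts 0-based read start positions.
#' @param read_length Read length (bp).
#' @param window Window size (bp).
#' @param stack_fold Stacking threshold as a fold of mean window coverage.
#' @param gap_frac Maximum tolerated fraction of zero-coverage windows.
#'
#' @return List: `flag`, plus diagnostics `max_fold` (max window coverage
#'   over mean), `zero_frac`, `window_coverage`, `mean_coverage`.
#' @export
coverage_evenness_flag <- function(genome_length, read_starts, read_length = 100L,
                                   window = 1000L, stack_fold = 10,
                                   gap_frac = 0.5) {
  if (window > genome_length) stop("window must not exceed genome_length")
  if (length(read_starts) == 0) stop("read_starts must be nonempty")
  if (any(read_starts < 0 | read_starts >= genome_length))
    stop("read positions must be in [0, genome_length)")
  n_win <- ceiling(genome_length / window)
  win <- pmin(read_starts %/% window + 1L, n_win)
  cnt <- tabulate(win, nbins = n_win)
  win_len <- c(rep(window, n_win - 1L), genome_length - (n_win - 1L) * window)
  cov <- cnt * read_length / win_len
  mean_cov <- length(read_starts) * read_length / genome_length
  max_fold <- max(cov) / mean_cov
  zero_frac <- mean(cnt == 0)
  list(flag = (max_fold > stack_fold) || (zero_frac > gap_frac),
       max_fold = max_fold, zero_frac = zero_frac,
       window_coverage = cov, mean_coverage = mean_cov)
}
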