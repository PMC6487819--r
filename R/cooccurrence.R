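#' Permutation-null co-occurrence network
#'
#' Scores the association between every pair of taxa against a null model
#' that preserves each taxon's abundance distribution: the observed
#' pairwise correlation of abundance vectors is compared to `n_null` null
#' tables in which each taxon's vector is independently permuted across
#' samples. The score is a standardized effect size,
#' `(observed - null mean) / null sd`; p-values are empirical and
#' two-sided with the add-one correction, and q-values are
#' Benjamini-Hochberg over all taxon pairs.
#'
#' The RNG protocol is fixed and documented so results are reproducible
#' bit-for-bit given `seed`: after `set.seed(seed)`, each null replicate
#' draws `U = matrix(runif(n * m), n, m)` and permutes taxon row `i` by
#' `order(U[i, ])`. Tail counts for the empirical p-values use a 1e-9
#' comparison tolerance so they are insensitive to last-ulp differences
#' between equivalent correlation implementations.
#'
#' @param counts taxa x samples matrix (raw counts or normalized).
#' @param n_null Number of null replicates (default 999).
#' @param seed RNG seed.
#' @param score_kind `"spearman"` (default; correlations computed on
#'   within-taxon ranks, robust to heavy-tailed counts) or `"pearson"`.
#'
#' @return Object of class `cooc_matrix`: list with symmetric matrices
#'   `score`, `p`, `q`, `obs` (raw correlation), plus `n_null` and
#'   `score_kind`. Diagonals are `NA`; zero-variance taxa yield `NA` rows.
#' @export
cooccurrence_network <- function(counts, n_null = 999, seed = NULL,
                                 score_kind = c("spearman", "pearson")) {
  score_kind <- match.arg(score_kind)
  n <- nrow(counts); m <- ncol(counts)
  if (n < 2) stop("need at least 2 taxa")
  if (m < 4) stop("need at least 4 samples")
  X <- counts
  if (score_kind == "spearman")
    X <- t(apply(X, 1, rank))
  X <- matrix(as.numeric(X), n, m, dimnames = dimnames(counts))

  ## correlations via one-time row standardization: permuting a row leaves
  ## its mean/sd unchanged, so cor(Xp) = tcrossprod of the permuted Z rows
  Xc <- X - rowMeans(X)
  Z <- Xc / sqrt(rowSums(Xc * Xc))   # zero-variance rows become NaN
  obs <- tcrossprod(Z)
  s1 <- matrix(0, n, n); s2 <- matrix(0, n, n)
  cnt_ge <- matrix(0, n, n); cnt_le <- matrix(0, n, n)
  if (!is.null(seed)) set.seed(seed)
  row_idx <- seq_len(n)
  key <- rep.int(row_idx, m)
  for (b in seq_len(n_null)) {
    o <- order(key + stats::runif(n * m))
    P <- matrix((o - 1L) %/% n + 1L, nrow = n, byrow = TRUE)
    Zp <- matrix(Z[(P - 1L) * n + row_idx], n, m)
    C <- tcrossprod(Zp)
    cooc_accum(s1, s2, cnt_ge, cnt_le, C, obs, 1e-9)
  }
  null_mean <- s1 / n_null
  null_sd <- sqrt(pmax(s2 / n_null - null_mean^2, 0) * n_null / (n_null - 1))
  score <- (obs - null_mean) / null_sd
  score[!is.finite(score)] <- NA
  p <- 2 * pmin((cnt_ge + 1) / (n_null + 1), (cnt_le + 1) / (n_null + 1))
  p <- pmin(p, 1)
  p[is.na(obs)] <- NA
  diag(score) <- diag(p) <- NA

  q <- matrix(NA_real_, n, n, dimnames = dimnames(p))
  ut <- upper.tri(p)
  ok <- ut & !is.na(p) & !is.na(score)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q[lower.tri(q)] <- t(q)[lower.tri(q)]

  dimnames(score) <- dimnames(p) <- dimnames(q) <-
    list(rownames(counts), rownames(counts))
  structure(list(score = score, p = p, q = q, obs = obs,
                 n_null = n_null, score_kind = score_kind),
            class = "cooc_matrix")
}

#' @export
print.cooc_matrix <- function(x, alpha = 0.05, ...) {
  n <- nrow(x$score)
  sig <- sum(x$q[upper.tri(x$q)] < alpha, na.rm = TRUE)
  cat(sprintf("Co-occurrence matrix: %d taxa, %d null replicates (%s)\n",
              n, x$n_null, x$score_kind))
  cat(sprintf("  %d / %d pairs significant at q < %g\n",
              sig, sum(!is.na(x$q[upper.tri(x$q)])), alpha))
  invisible(x)
}

#' Guilt-by-association contaminant expansion
#'
#' Given confirmed contaminant seed taxa, selects the taxa in the top
#' `top_frac` (default 10%) by absolute *significant* co-occurrence score
#' with any seed, and returns them unioned with the seeds as the removal
#' set. Significance (`q < alpha`) gates the candidate pool before the
#' top-fraction cut. Ties break deterministically by (score descending,
#' label ascending).
#'
#' @param cooc A [cooccurrence_network()] result.
#' @param seed_taxa Confirmed contaminant labels (must be in the matrix).
#' @param top_frac Fraction of significant partners to remove.
#' @param alpha Significance level on q-values.
#'
#' @return Character vector: seeds followed by the selected partners.
#' @export
expand_contaminants <- function(cooc, seed_taxa, top_frac = 0.10, alpha = 0.05) {
  taxa <- rownames(cooc$score)
  missing <- setdiff(seed_taxa, taxa)
  if (length(missing))
    stop("seed taxa absent from co-occurrence matrix: ",
         paste(missing, collapse = ", "))
  others <- setdiff(taxa, seed_taxa)
  if (!length(others)) return(seed_taxa)
  qs <- cooc$q[seed_taxa, others, drop = FALSE]
  sc <- abs(cooc$score[seed_taxa, others, drop = FALSE])
  sc[is.na(qs) | qs >= alpha] <- NA
  best <- apply(sc, 2, function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  cand <- others[!is.na(best)]
  if (!length(cand)) return(seed_taxa)
  bs <- best[!is.na(best)]
  ord <- order(-bs, cand)
  k <- ceiling(top_frac * length(cand))
  c(seed_taxa, cand[ord][seq_len(min(k, length(cand)))])
}

#' Apply a removal set to a count table
#'
#' Drops the removal-set rows and reports samples left with no reads at
#' all (candidates for exclusion from downstream analysis).
#'
#' @param counts taxa x samples matrix.
#' @param removal Taxon labels to drop (absent labels ignored).
#' @return List: `counts` (filtered), `removed` (labels actually dropped),
#'   `excluded_samples` (samples whose remaining column sum is 0).
#' @export
apply_removal <- function(counts, removal) {
  keep <- !(rownames(counts) %in% removal)
  out <- counts[keep, , drop = FALSE]
  excluded <- colnames(out)[colSums(out) == 0]
  list(counts = out,
       removed = intersect(rownames(counts), removal),
       excluded_samples = excluded)
}
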