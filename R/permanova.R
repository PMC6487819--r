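#' PERMANOVA on a distance matrix
#'
#' Sequential (Type I) partition of the distance-based sum of squares over
#' an ordered list of covariates, with a permutation test of the pseudo-F
#' statistic (free permutation of samples, the classic `adonis` behavior;
#' `p = (#{permuted F >= observed} + 1) / (n_perm + 1)`). Backed by
#' `vegan::adonis2(by = "terms")`.
#'
#' @param d A `dist` object.
#' @param metadata Data.frame with one row per sample of `d`, aligned with
#'   the distance labels via a `sample` column (or taken row-aligned when
#'   absent).
#' @param terms Ordered character vector of covariate names in `metadata`.
#' @param n_perm Number of permutations (default 9999), or a permutation
#'   matrix (one permutation of `1:n` per row), e.g. the complete
#'   enumeration for small designs.
#' @param seed RNG seed for the permutations.
#' @return Data.frame of class `permanova_result`: term, df, F, r2, p,
#'   with Residual and Total rows; r2 column sums to 1 over
#'   terms + residual.
#' @export
permanova <- function(d, metadata, terms, n_perm = 9999, seed = NULL) {
  d <- stats::as.dist(d)
  labs <- attr(d, "Labels")
  if (!is.null(labs) && "sample" %in% names(metadata)) {
    idx <- match(labs, metadata$sample)
    if (anyNA(idx)) stop("metadata missing samples: ",
                         paste(labs[is.na(idx)], collapse = ", "))
    metadata <- metadata[idx, , drop = FALSE]
  }
  missing <- setdiff(terms, names(metadata))
  if (length(missing)) stop("terms not in metadata: ",
                            paste(missing, collapse = ", "))
  df <- as.data.frame(metadata)[, terms, drop = FALSE]
  n <- attr(d, "Size")
  model_df <- sum(vapply(df, function(v)
    if (is.numeric(v)) 1L else length(unique(v)) - 1L, integer(1)))
  if (n - 1L - model_df <= 0L) stop("confounded model: zero residual df")
  fm <- stats::as.formula(paste("d ~", paste(terms, collapse = " + ")))
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::adonis2(fm, data = df, permutations = n_perm, by = "terms")
  out <- data.frame(term = rownames(fit), df = fit$Df, F = fit$F,
                    r2 = fit$R2, p = fit$`Pr(>F)`, stringsAsFactors = FALSE)
  ## aliased (fully confounded) terms explain nothing: report them as zero
  dropped <- setdiff(terms, out$term)
  if (length(dropped)) {
    zero <- data.frame(term = dropped, df = 0L, F = NA_real_, r2 = 0,
                       p = NA_real_, stringsAsFactors = FALSE)
    out <- rbind(out[match(setdiff(terms, dropped), out$term), ], zero,
                 out[out$term %in% c("Residual", "Total"), ])
  }
  attr(out, "n_perm") <- if (is.matrix(n_perm)) nrow(n_perm) else n_perm
  class(out) <- c("permanova_result", "data.frame")
  out
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA (sequential SS, %d permutations)\n", attr(x, "n_perm")))
  y <- `class<-`(x, "data.frame")
  y$F <- round(y$F, 3); y$r2 <- round(y$r2, 4)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Homogeneity of group dispersions
#'
#' Distance of each sample to its group centroid in principal-coordinate
#' space, followed by a one-way ANOVA on those distances (the
#' `betadisper` procedure), used both as a check that PERMANOVA results
#' are not driven by unequal within-group spread and as a biological
#' measure of between-individual variability per group.
#'
#' @param d A `dist` object.
#' @param groups Group label per sample (>= 2 groups, each >= 2 samples).
#' @return List of class `dispersion_test`: `F`, `p`, `df`,
#'   `group_means` (mean distance-to-centroid per group), `model` (the
#'   underlying `betadisper` fit).
#' @export
dispersion_test <- function(d, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("singleton group(s): ",
      paste(names(which(table(groups) < 2)), collapse = ", "))
  bd <- vegan::betadisper(stats::as.dist(d), groups, type = "centroid")
  an <- stats::anova(bd)
  structure(list(F = an$`F value`[1], p = an$`Pr(>F)`[1],
                 df = an$Df,
                 group_means = tapply(bd$distances, groups, mean),
                 model = bd),
            class = "dispersion_test")
}

#' @export
print.dispersion_test <- function(x, ...) {
  cat(sprintf("Group dispersion homogeneity: F(%d, %d) = %.3f, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p))
  print(round(x$group_means, 4))
  invisible(x)
}
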