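#' Per-sample diatom proportion
#'
#' Raw diatom read counts converted to the proportion of the total number
#' of sequencing reads per sample.
#'
#' @param metadata Data.frame with `diatom_reads` and `total_reads`.
#' @return Named numeric vector of proportions.
#' @export
diatom_proportion <- function(metadata) {
  if (any(metadata$total_reads <= 0)) stop("total_reads must be positive")
  if (any(metadata$diatom_reads > metadata$total_reads))
    stop("diatom_reads cannot exceed total_reads")
  stats::setNames(metadata$diatom_reads / metadata$total_reads,
                  metadata$sample)
}

#' Quasi-Poisson GLM (log link)
#'
#' Fits a Poisson log-link GLM by IRLS and estimates the dispersion from
#' the Pearson chi-square, `phi = sum(pearson residuals^2) / (n - p)`;
#' standard errors are the Poisson SEs inflated by `sqrt(phi)` and tests
#' are t-tests on `n - p` degrees of freedom. A thin, classed wrapper
#' around `stats::glm(family = quasipoisson)` with strict rank and
#' convergence checks.
#'
#' @param formula Model formula.
#' @param data Data.frame.
#' @param offset Optional offset vector (log scale), e.g.
#'   `log(total_reads)` to model a count response as a rate.
#' @return Object of class `qp_glm`: `coefficients` (data.frame: term,
#'   beta, se, t, p), `dispersion`, `deviance`, `n`, `fit` (the glm).
#' @export
quasipoisson_glm <- function(formula, data, offset = NULL) {
  mf <- stats::model.frame(formula, data = data)
  X <- stats::model.matrix(formula, data = data)
  if (nrow(X) <= ncol(X))
    stop("need more observations than parameters (n > p)")
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix")
  if (!is.null(offset)) {
    data$.off_ <- offset
    fit <- stats::glm(formula, data = data,
                      family = stats::quasipoisson(link = "log"),
                      offset = .off_)
  } else {
    fit <- stats::glm(formula, data = data,
                      family = stats::quasipoisson(link = "log"))
  }
  if (!fit$converged) stop("IRLS failed to converge; deviance trace: ",
                           paste(round(fit$deviance, 4), collapse = ", "))
  mu <- stats::fitted(fit)
  y <- fit$y
  df_res <- nrow(X) - ncol(X)
  phi <- sum((y - mu)^2 / mu) / df_res           # Pearson dispersion
  se_pois <- summary(fit, dispersion = 1)$coefficients[, 2]
  beta <- stats::coef(fit)
  se <- sqrt(phi) * se_pois
  tval <- beta / se
  out <- data.frame(term = names(beta), beta = unname(beta),
                    se = unname(se), t = unname(tval),
                    p = 2 * stats::pt(-abs(tval), df_res),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = out, dispersion = phi,
                 deviance = stats::deviance(fit), n = nrow(X), fit = fit),
            class = "qp_glm")
}

#' @export
print.qp_glm <- function(x, ...) {
  cat(sprintf("Quasi-Poisson GLM (log link), n = %d, dispersion = %.3f\n",
              x$n, x$dispersion))
  y <- x$coefficients
  y$beta <- signif(y$beta, 4); y$se <- signif(y$se, 3)
  y$t <- round(y$t, 2); y$p <- signif(y$p, 3)
  print(y, row.names = FALSE)
  invisible(x)
}

#' @export
coef.qp_glm <- function(object, ...) {
  stats::setNames(object$coefficients$beta, object$coefficients$term)
}

#' Diatom-load association models
#'
#' Fits the suite of quasi-Poisson associations between per-sample diatom
#' load and (i) region (Antarctic vs North Pacific, coded Antarctic = 1 so
#' a positive coefficient means higher Antarctic diatom load),
#' (ii) pathogen abundance, (iii) pathogen presence (binary) and (iv)
#' presence of at least one algae-associated taxon. All models share the
#' covariates longitude, log species-level read count (library-size
#' control) and log human-mapped reads (human-contamination control). The
#' response is the diatom read count with `log(total_reads)` offset —
#' identical coefficients, under the log link, to modelling the diatom
#' proportion directly (`use_offset = FALSE` fits the raw proportion for
#' comparison).
#'
#' @param metadata Sample metadata (sample, latitude, longitude,
#'   total_reads, human_reads, diatom_reads).
#' @param counts taxa x samples table used for pathogen/algae covariates
#'   and the species-level read total.
#' @param algae_taxa Labels of algae-associated taxa (missing ones are
#'   reported and skipped).
#' @param pathogen_taxon Label of the pathogen taxon.
#' @param use_offset Model counts with log-total offset (default) or the
#'   raw proportion.
#' @return List of class `diatom_models`: `models` (named list of
#'   [quasipoisson_glm()] fits), `skipped` (models dropped for degenerate
#'   binary covariates), `missing_taxa`.
#' @export
diatom_association_models <- function(metadata, counts, algae_taxa,
                                      pathogen_taxon, use_offset = TRUE) {
  idx <- match(metadata$sample, colnames(counts))
  if (anyNA(idx)) stop("counts missing samples: ",
                       paste(metadata$sample[is.na(idx)], collapse = ", "))
  counts <- counts[, idx, drop = FALSE]
  missing_taxa <- setdiff(c(pathogen_taxon, algae_taxa), rownames(counts))
  algae_taxa <- intersect(algae_taxa, rownames(counts))
  has_pathogen <- pathogen_taxon %in% rownames(counts)

  df <- data.frame(
    y = if (use_offset) metadata$diatom_reads else
      metadata$diatom_reads / metadata$total_reads,
    antarctic = as.integer(metadata$latitude < 0),
    longitude = metadata$longitude,
    log_species_reads = log(pmax(colSums(counts), 1)),
    log_human_reads = log1p(metadata$human_reads)
  )
  off <- if (use_offset) log(metadata$total_reads) else NULL
  covars <- "longitude + log_species_reads + log_human_reads"

  models <- list(); skipped <- character(0)
  fit1 <- function(extra) quasipoisson_glm(
    stats::as.formula(paste("y ~", extra, "+", covars)), df, offset = off)

  degenerate <- function(v) length(unique(v)) < 2
  if (degenerate(df$antarctic)) skipped <- c(skipped, "region")
  else models$region <- fit1("antarctic")

  if (has_pathogen) {
    df$pathogen_abund <- counts[pathogen_taxon, ]
    df$pathogen_presence <- as.integer(df$pathogen_abund > 0)
    if (degenerate(df$pathogen_abund)) skipped <- c(skipped, "pathogen_abundance")
    else models$pathogen_abundance <- fit1("pathogen_abund")
    if (degenerate(df$pathogen_presence)) skipped <- c(skipped, "pathogen_presence")
    else models$pathogen_presence <- fit1("pathogen_presence")
  } else skipped <- c(skipped, "pathogen_abundance", "pathogen_presence")

  if (length(algae_taxa)) {
    df$algae_presence <- as.integer(
      colSums(counts[algae_taxa, , drop = FALSE] > 0) > 0)
    if (degenerate(df$algae_presence)) skipped <- c(skipped, "algae_presence")
    else models$algae_presence <- fit1("algae_presence")
  } else skipped <- c(skipped, "algae_presence")

  structure(list(models = models, skipped = skipped,
                 missing_taxa = missing_taxa),
            class = "diatom_models")
}

#' @export
print.diatom_models <- function(x, ...) {
  cat("Diatom-load association models\n")
  for (nm in names(x$models)) {
    co <- x$models[[nm]]$coefficients[2, ]
    cat(sprintf("  %-20s beta = %6.3f  SE = %.3f  p = %.3g\n",
                nm, co$beta, co$se, co$p))
  }
  if (length(x$skipped))
    cat("  skipped (degenerate):", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' Colour grade vs diatom load
#'
#' Tests for a monotone increase of diatom proportion along an ordinal
#' skin colour grading (clean -> prominent) with a one-sided rank trend
#' test: Kendall correlation between grade ranks and diatom proportion
#' (normal approximation with tie correction), plus per-grade medians.
#'
#' @param metadata Metadata with `colour_grade`, `diatom_reads`,
#'   `total_reads`; rows with `NA` grade are dropped.
#' @param grade_levels Ordered grade levels, lowest first.
#' @return List: `p` (one-sided), `tau`, `medians` (per grade), `n`.
#' @export
colour_grade_association <- function(metadata,
                                     grade_levels = c("clean", "slight",
                                                      "moderate", "prominent")) {
  keep <- !is.na(metadata$colour_grade)
  md <- metadata[keep, , drop = FALSE]
  g <- factor(md$colour_grade, levels = grade_levels, ordered = TRUE)
  if (anyNA(g)) stop("unknown colour grades: ",
                     paste(setdiff(md$colour_grade, grade_levels), collapse = ", "))
  tab <- table(droplevels(g))
  if (sum(tab >= 2) < 2 || nlevels(droplevels(g)) < 2)
    stop("need >= 2 grade levels with >= 2 samples each")
  prop <- md$diatom_reads / md$total_reads
  ct <- suppressWarnings(stats::cor.test(as.numeric(g), prop,
                                         method = "kendall", exact = FALSE,
                                         alternative = "greater"))
  list(p = ct$p.value, tau = unname(ct$estimate),
       medians = tapply(prop, g, stats::median), n = length(prop))
}
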