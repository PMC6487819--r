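test_that("diatom proportion is a plain ratio with guards", {
  md <- data.frame(sample = c("a", "b", "c"),
                   diatom_reads = c(0, 10, 55),
                   total_reads = c(100, 1000, 500))
  p <- diatom_proportion(md)
  expect_equal(unname(p), c(0, 0.01, 0.11))
  md$total_reads[1] <- 0
  expect_error(diatom_proportion(md), "positive")
  md$total_reads[1] <- 10; md$diatom_reads[1] <- 20
  expect_error(diatom_proportion(md), "exceed")
})

test_that("quasi-Poisson GLM matches closed forms and the Newton oracle", {
  # intercept-only with equal counts: beta0 = log(mean), Pearson dispersion
  df <- data.frame(y = rep(7, 10))
  fit <- quasipoisson_glm(y ~ 1, df)
  expect_equal(fit$coefficients$beta, log(7), tolerance = 1e-10)
  expect_equal(fit$dispersion, 0, tolerance = 1e-10)

  # 20-row fixture vs brute-force Newton optimizer
  set.seed(41)
  df2 <- data.frame(x = rnorm(20), z = runif(20))
  df2$y <- rpois(20, exp(0.5 + 0.8 * df2$x - 0.4 * df2$z))
  fit2 <- quasipoisson_glm(y ~ x + z, df2)
  X <- model.matrix(~ x + z, df2)
  expect_equal(unname(coef(fit2)), unname(newton_poisson(X, df2$y)),
               tolerance = 1e-8)

  # dispersion equals the Pearson formula
  mu <- fitted(fit2$fit)
  phi <- sum((df2$y - mu)^2 / mu) / (20 - 3)
  expect_equal(fit2$dispersion, phi, tolerance = 1e-10)

  # with offset: count response with log-total offset equals proportion response
  df2$tot <- round(runif(20, 500, 5000))
  df2$cnt <- rpois(20, df2$tot * exp(-4 + 0.5 * df2$x))
  f_off <- quasipoisson_glm(cnt ~ x, df2, offset = log(df2$tot))
  b_prop <- newton_poisson(model.matrix(~ x, df2), df2$cnt, log(df2$tot))
  expect_equal(unname(coef(f_off)), unname(b_prop), tolerance = 1e-8)

  expect_error(quasipoisson_glm(y ~ x + I(2 * x), df2), "rank-deficient")
  expect_error(quasipoisson_glm(y ~ x + z, df2[1:3, ]), "n > p")
})

test_that("Wald intervals reach nominal coverage under overdispersion", {
  # quasi-Poisson data via negative binomial with phi ~ 3 at mu = e
  set.seed(42)
  n <- 200; b0 <- 1.0; b1 <- 0.5
  cover <- replicate(500, {
    x <- rnorm(n)
    mu <- exp(b0 + b1 * x)
    size <- mu / 2            # Var = mu + mu^2/size = 3 mu
    y <- rnbinom(n, mu = mu, size = size)
    fit <- quasipoisson_glm(y ~ x, data.frame(x = x, y = y))
    co <- fit$coefficients[2, ]
    crit <- qt(0.975, n - 2)
    (co$beta - crit * co$se) <= b1 && b1 <= (co$beta + crit * co$se)
  })
  expect_gt(mean(cover), 0.95 - 3 * sqrt(0.05 * 0.95 / 500))
  expect_lt(mean(cover), 0.95 + 3 * sqrt(0.05 * 0.95 / 500))
})

test_that("diatom association models recover the planted effects", {
  sim <- generate_profiles(synthetic_scenario(), seed = 43)
  md <- sim$metadata
  algae <- grep("^algae_", rownames(sim$counts), value = TRUE)
  dm <- diatom_association_models(md, sim$counts, algae_taxa = algae,
                                  pathogen_taxon = "Tenacibaculum_dicentrarchi")
  expect_true(all(c("region", "pathogen_abundance", "pathogen_presence") %in%
                  names(dm$models)))
  # Antarctic ecotypes carry more diatom DNA: positive region coefficient
  reg <- dm$models$region$coefficients
  expect_gt(reg$beta[reg$term == "antarctic"], 0)
  # pathogen presence positively associated with diatom load
  pp <- dm$models$pathogen_presence$coefficients
  expect_gt(pp$beta[pp$term == "pathogen_presence"], 0)

  # missing taxa are reported, not fatal
  dm2 <- diatom_association_models(md, sim$counts, algae_taxa = "ghost_taxon",
                                   pathogen_taxon = "Tenacibaculum_dicentrarchi")
  expect_true("ghost_taxon" %in% dm2$missing_taxa)
  expect_true("algae_presence" %in% dm2$skipped)
})

test_that("pathogen-presence effect is powered; null effect is calibrated", {
  set.seed(44)
  reps <- 30
  det <- logical(reps); pnull <- numeric(reps)
  for (i in seq_len(reps)) {
    sim <- generate_profiles(synthetic_scenario(), seed = 4000 + i)
    dm <- diatom_association_models(sim$metadata, sim$counts,
            algae_taxa = grep("^algae_", rownames(sim$counts), value = TRUE),
            pathogen_taxon = "Tenacibaculum_dicentrarchi")
    co <- dm$models$pathogen_presence$coefficients
    det[i] <- co$p[co$term == "pathogen_presence"] < 0.05 &&
      co$beta[co$term == "pathogen_presence"] > 0

    sim0 <- generate_profiles(synthetic_scenario(diatom_effect = 0),
                              seed = 5000 + i)
    dm0 <- diatom_association_models(sim0$metadata, sim0$counts,
            algae_taxa = grep("^algae_", rownames(sim0$counts), value = TRUE),
            pathogen_taxon = "Tenacibaculum_dicentrarchi")
    co0 <- dm0$models$pathogen_presence$coefficients
    pnull[i] <- co0$p[co0$term == "pathogen_presence"]
  }
  expect_gte(mean(det), 0.9)
  expect_lte(mean(pnull < 0.05), 0.2)   # small-sample type-I stays moderate
})

test_that("colour grades track diatom load with a one-sided rank trend", {
  set.seed(45)
  md <- data.frame(sample = paste0("s", 1:24),
                   colour_grade = rep(c("clean", "slight", "moderate",
                                        "prominent"), each = 6),
                   total_reads = 1e5)
  load <- c(0.001, 0.003, 0.01, 0.03)[as.integer(factor(md$colour_grade,
            levels = c("clean", "slight", "moderate", "prominent")))]
  md$diatom_reads <- rpois(24, load * md$total_reads)
  res <- colour_grade_association(md)
  expect_lt(res$p, 0.01)
  expect_true(all(diff(res$medians) >= 0))

  # shuffled grades: p roughly uniform (check no systematic inflation)
  ps <- replicate(100, {
    md$colour_grade <- sample(md$colour_grade)
    colour_grade_association(md)$p
  })
  expect_gt(mean(ps < 0.05), 0.0)  # sanity: well-defined
  expect_lt(mean(ps < 0.05), 0.15)

  expect_error(colour_grade_association(
    data.frame(sample = "x", colour_grade = "clean",
               diatom_reads = 1, total_reads = 10)), "grade levels")
})
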