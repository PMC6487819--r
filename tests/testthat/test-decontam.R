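# -- frequency test ----------------------------------------------------------

test_that("taxa proportional to depth are not flagged; planted contaminants are", {
  set.seed(31)
  depth <- round(exp(runif(12, log(1e4), log(1e6))))
  md <- data.frame(sample = paste0("s", 1:12), total_reads = depth)
  cnt <- rbind(
    prop1 = round(depth * 0.002),          # scales with depth: benign
    prop2 = round(depth * 0.0005),
    contam = rpois(12, 300)                # constant absolute input
  )
  colnames(cnt) <- md$sample
  ft <- taxon_frequency_test(cnt, md)
  expect_false(ft$flagged[ft$taxon == "prop1"])
  expect_false(ft$flagged[ft$taxon == "prop2"])
  expect_true(ft$flagged[ft$taxon == "contam"])
  expect_lt(ft$statistic[ft$taxon == "contam"], 0)
})

test_that("frequency test agrees with a hand-rolled rank correlation + BH", {
  sim <- generate_profiles(small_scenario(), seed = 8)
  cnt <- filter_min_reads(sim$counts)
  md <- sim$metadata
  ft <- taxon_frequency_test(cnt, md)

  total <- md$total_reads[match(colnames(cnt), md$sample)]
  prop <- sweep(cnt, 2, total, "/")
  n <- ncol(cnt)
  stat <- p <- rep(NA_real_, nrow(cnt))
  for (j in seq_len(nrow(cnt))) {
    if (sd(prop[j, ]) == 0) next
    r <- cor(rank(prop[j, ]), rank(total))
    stat[j] <- r
    tv <- r * sqrt((n - 2) / (1 - r^2))
    p[j] <- 2 * pt(-abs(tv), n - 2)
  }
  q <- rep(1, nrow(cnt)); ok <- !is.na(p)
  q[ok] <- p.adjust(p[ok], "BH")
  expect_equal(ft$statistic, stat, tolerance = 1e-12)
  expect_equal(ft$q, q, tolerance = 1e-9)
  expect_equal(ft$flagged, !is.na(stat) & stat < 0 & q < 0.05)
})

test_that("constant-proportion taxa and tiny designs are handled", {
  # "const" holds exactly half the reads of every sample: zero-variance
  # proportion, so no statistic can be computed
  cnt <- matrix(c(5, 10, 15, 20, 1, 2, 3, 4), 2, 4, byrow = TRUE,
                dimnames = list(c("const", "var"), paste0("s", 1:4)))
  md <- data.frame(sample = paste0("s", 1:4), total_reads = c(10, 20, 30, 40))
  ft <- taxon_frequency_test(cnt, md)
  expect_true(is.na(ft$statistic[ft$taxon == "const"]))
  expect_equal(ft$q[ft$taxon == "const"], 1)
  expect_false(ft$flagged[ft$taxon == "const"])
  expect_error(taxon_frequency_test(cnt[, 1:3], md[1:3, ]), "4 samples")
})

test_that("frequency-test false-flag rate stays below alpha on null tables", {
  set.seed(32)
  frac <- replicate(200, {
    depth <- round(exp(runif(15, log(1e4), log(1e6))))
    md <- data.frame(sample = paste0("s", 1:15), total_reads = depth)
    base <- rlnorm(30, 0, 1.5)
    cnt <- sapply(depth, function(d)
      rmultinom(1, round(d * 0.02), base)[, 1])  # everything scales with depth
    rownames(cnt) <- paste0("t", 1:30); colnames(cnt) <- md$sample
    ft <- taxon_frequency_test(cnt, md)
    mean(ft$flagged)
  })
  expect_lte(mean(frac), 0.05)
})

# -- co-occurrence network ---------------------------------------------------

test_that("co-occurrence scores equal the direct-loop oracle", {
  set.seed(33)
  cnt <- matrix(rpois(120, 15), 10, 12,
                dimnames = list(paste0("t", 1:10), paste0("s", 1:12)))
  got <- cooccurrence_network(cnt, n_null = 99, seed = 77)
  want <- cooc_oracle(cnt, n_null = 99, seed = 77)
  expect_equal(unname(got$score), want$score, tolerance = 1e-12)
  expect_equal(unname(got$p), want$p, tolerance = 1e-12)
})

test_that("co-occurrence matrix is symmetric, order-invariant, with NA diagonal", {
  set.seed(34)
  cnt <- matrix(rpois(48, 10), 8, 6,
                dimnames = list(paste0("t", 1:8), paste0("s", 1:6)))
  cc <- cooccurrence_network(cnt, n_null = 199, seed = 5)
  expect_true(all(is.na(diag(cc$score))))
  expect_equal(cc$score, t(cc$score))
  expect_equal(cc$q, t(cc$q))
  expect_true(all(cc$q >= 0 & cc$q <= 1, na.rm = TRUE))

  # permuting the sample order leaves the observed correlations unchanged
  # exactly; the standardized scores differ only by null Monte-Carlo error
  cc2 <- cooccurrence_network(cnt[, c(4, 1, 6, 2, 5, 3)], n_null = 199, seed = 5)
  expect_equal(cc2$obs, cc$obs, tolerance = 1e-12)
  expect_lt(max(abs(cc2$score - cc$score), na.rm = TRUE), 0.5)

  # identical taxa pair: maximal positive association, p near the floor
  set.seed(36)
  cnt12 <- matrix(rpois(96, 10), 8, 12,
                  dimnames = list(paste0("t", 1:8), paste0("s", 1:12)))
  twin <- rbind(cnt12, t9 = cnt12[1, ])
  cc3 <- cooccurrence_network(twin, n_null = 999, seed = 6)
  pair <- cc3$score["t1", "t9"]
  expect_equal(cc3$obs["t1", "t9"], 1)
  expect_equal(pair, max(cc3$score, na.rm = TRUE))
  expect_lte(cc3$p["t1", "t9"], 0.01)
  expect_equal(cc3$q["t1", "t9"], min(cc3$q, na.rm = TRUE))

  # zero-variance taxon yields NA scores
  flat <- rbind(cnt, flat = rep(3, 6))
  cc4 <- cooccurrence_network(flat, n_null = 99, seed = 7)
  expect_true(all(is.na(cc4$score["flat", ])))
})

test_that("independent taxa are rarely called significant (FDR calibration)", {
  set.seed(35)
  frac <- replicate(100, {
    cnt <- matrix(rpois(15 * 20, 20), 15, 20,
                  dimnames = list(paste0("t", 1:15), paste0("s", 1:20)))
    cc <- cooccurrence_network(cnt, n_null = 199)
    q <- cc$q[upper.tri(cc$q)]
    mean(q < 0.05, na.rm = TRUE)
  })
  expect_lte(mean(frac), 0.05)
})

# -- guilt-by-association expansion ------------------------------------------

test_that("expansion takes the significant top fraction, seeds included", {
  n <- 30
  sc <- matrix(NA_real_, n, n); qq <- matrix(NA_real_, n, n)
  labs <- c("seed", sprintf("t%02d", 1:(n - 1)))
  dimnames(sc) <- dimnames(qq) <- list(labs, labs)
  sc["seed", -1] <- seq(29, 1) / 10      # t01 strongest ... t29 weakest
  sc[-1, "seed"] <- sc["seed", -1]
  qq["seed", -1] <- qq[-1, "seed"] <- c(rep(0.01, 20), rep(0.5, 9))
  cooc <- structure(list(score = sc, q = qq, n_null = 99), class = "cooc_matrix")

  # 20 significant partners -> top 10% = 2, plus the seed
  expect_equal(expand_contaminants(cooc, "seed"),
               c("seed", "t01", "t02"))
  # monotone nesting in top_frac
  r1 <- expand_contaminants(cooc, "seed", top_frac = 0.1)
  r2 <- expand_contaminants(cooc, "seed", top_frac = 0.3)
  expect_true(all(r1 %in% r2))
  # no significant partners -> seeds only
  qq2 <- qq; qq2[] <- 0.9
  cooc2 <- structure(list(score = sc, q = qq2), class = "cooc_matrix")
  expect_equal(expand_contaminants(cooc2, "seed"), "seed")
  expect_error(expand_contaminants(cooc, "nope"), "absent")
})

test_that("apply_removal drops rows, reports emptied samples, is idempotent", {
  cnt <- toy_counts()
  r <- apply_removal(cnt, c("t1", "t3", "ghost"))
  expect_equal(rownames(r$counts), c("t2", "t4", "t5"))
  expect_equal(r$removed, c("t1", "t3"))
  expect_equal(r$excluded_samples, character(0))

  # removing everything a sample has flags it for exclusion
  cnt2 <- matrix(c(5, 0, 0, 8, 2, 1), 3, 2,
                 dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  r2 <- apply_removal(cnt2, "a")
  expect_equal(r2$excluded_samples, "s1")

  # identity and idempotence
  expect_equal(apply_removal(cnt, character(0))$counts, cnt)
  twice <- apply_removal(apply_removal(cnt, "t1")$counts, "t1")
  expect_equal(twice$counts, apply_removal(cnt, "t1")$counts)
})

# -- identity profiling and lane consistency ---------------------------------

test_that("identity summary counts thresholds correctly", {
  s <- identity_summary(c(100, 100, 96), thresholds = 97)
  expect_equal(s$eq100, 2)
  expect_equal(unname(s$ge["ge97"]), 2)
  s0 <- identity_summary(numeric(0))
  expect_equal(s0$n, 0); expect_equal(s0$eq100, 0)
  expect_error(identity_summary(c(50, 101)), "within")

  # constructed 527-contig profile: 245 exact, 505 at >= 97
  ids <- c(rep(100, 245), runif(260, 97, 99.99), runif(22, 90, 96.9))
  s527 <- identity_summary(ids, thresholds = 97)
  expect_equal(s527$n, 527)
  expect_equal(s527$eq100, 245)
  expect_equal(unname(s527$ge["ge97"]), 505)
})

test_that("lane CV is zero for identical lanes and matches the hand formula", {
  same <- rbind(c(0.2, 0.4), c(0.2, 0.4))
  expect_equal(lane_consistency_cv(same)$cv, 0)
  one <- lane_consistency_cv(matrix(c(0.1, 0.2), 2, 1))
  expect_equal(one$cv, sd(c(0.1, 0.2)) / mean(c(0.1, 0.2)))
  z <- lane_consistency_cv(matrix(c(0, 0, 0.1, 0.3), 2, 2))
  expect_true(is.na(z$per_sample[1]))
  expect_error(lane_consistency_cv(matrix(1, 1, 3)), "2 lanes")
})

test_that("multinomial lane splits give small CVs that shrink with depth", {
  sim <- generate_profiles(small_scenario(), seed = 13)
  top <- names(sort(rowSums(sim$counts), decreasing = TRUE))[1]
  lane_tot <- apply(sim$lane_counts, c(2, 3), sum)
  rel <- t(sim$lane_counts[top, , ] / lane_tot)
  cv <- lane_consistency_cv(rel)
  expect_lt(cv$cv, 0.25)
  # deeper samples have tighter lane agreement
  depth <- colSums(sim$counts)
  shallow <- mean(cv$per_sample[depth < median(depth)], na.rm = TRUE)
  deep <- mean(cv$per_sample[depth >= median(depth)], na.rm = TRUE)
  expect_lt(deep, shallow)
})
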