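test_that("Bray-Curtis and binary Jaccard match their closed forms", {
  x <- c(1, 2, 0); y <- c(0, 2, 4)
  cnt <- cbind(s1 = x, s2 = y); rownames(cnt) <- paste0("t", 1:3)
  bc <- as.matrix(community_distance(cnt, "bray_curtis"))
  expect_equal(bc["s1", "s2"], sum(abs(x - y)) / sum(x + y))  # 5/9
  ja <- as.matrix(community_distance(cnt, "jaccard_binary"))
  expect_equal(ja["s1", "s2"], 1 - 1 / 3)                     # share 1 of 3 taxa

  # identical samples -> 0; disjoint -> 1 (both metrics)
  dup <- cbind(s1 = x, s2 = x); rownames(dup) <- paste0("t", 1:3)
  dis <- cbind(s1 = c(3, 0, 1, 0), s2 = c(0, 2, 0, 9))
  rownames(dis) <- paste0("t", 1:4)
  for (m in c("bray_curtis", "jaccard_binary")) {
    expect_equal(as.matrix(community_distance(dup, m))["s1", "s2"], 0)
    expect_equal(as.matrix(community_distance(dis, m))["s1", "s2"], 1)
    d <- community_distance(toy_counts(), m)
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(attr(d, "metric"), m)
  }
})

test_that("distance matrices round-trip through TSV with their metric tag", {
  d <- community_distance(toy_counts(), "jaccard_binary")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_dist_tsv(d, f)
  d2 <- read_dist_tsv(f)
  expect_equal(attr(d2, "metric"), "jaccard_binary")
  expect_equal(as.matrix(d2), as.matrix(d), tolerance = 1e-12)
})

test_that("PCoA embeds Euclidean data exactly and matches a dense eigensolver", {
  set.seed(4)
  pts <- matrix(rnorm(10), 5, 2, dimnames = list(paste0("s", 1:5), NULL))
  d <- dist(pts)
  ord <- pcoa(d)
  # two positive eigenvalues carry all the variation; rest ~ 0
  expect_equal(ncol(ord$coordinates), 2)
  expect_true(all(abs(ord$eigenvalues[-(1:2)]) < 1e-8))
  expect_equal(length(ord$negative_eigenvalues), 0)
  # inter-point distances reconstructed to 1e-8
  expect_lt(max(abs(dist(ord$coordinates) - d)), 1e-8)

  # eigenvalues equal a brute-force Gower double-centering + eigen()
  D2 <- as.matrix(d)^2
  n <- nrow(D2)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% D2 %*% J
  ev <- eigen(G, symmetric = TRUE)$values
  expect_equal(sort(ord$eigenvalues, decreasing = TRUE)[1:2], ev[1:2],
               tolerance = 1e-10)

  # sample-order invariance: permuting samples permutes coordinates
  perm <- c(3, 1, 5, 2, 4)
  ord2 <- pcoa(dist(pts[perm, ]))
  flip <- sign(diag(cor(ord2$coordinates[rownames(ord$coordinates), ],
                        ord$coordinates)))
  expect_equal(sweep(ord2$coordinates[rownames(ord$coordinates), ], 2, flip, "*"),
               ord$coordinates, tolerance = 1e-8)

  expect_error(pcoa(matrix(c(0, NA, NA, 0), 2, 2)), "NA")
})

test_that("taxon loadings equal the brute-force weighted-average score", {
  set.seed(9)
  cnt <- matrix(rpois(24, 20), 6, 4,
                dimnames = list(paste0("t", 1:6), paste0("s", 1:4)))
  ord <- pcoa(community_distance(cnt, "bray_curtis"))
  L <- taxon_loadings(ord, cnt, n_axes = 2)
  w <- tss_normalize(cnt)
  for (j in 1:6) for (a in 1:2) {
    want <- sum(w[j, ] * ord$coordinates[, a]) / sum(w[j, ])
    expect_equal(L[j, a], want)
  }

  # taxon present only in positive-axis samples gets a positive loading
  pos <- rownames(ord$coordinates)[ord$coordinates[, 1] > 0]
  cnt2 <- rbind(cnt, marker = ifelse(colnames(cnt) %in% pos, 50, 0))
  L2 <- taxon_loadings(pcoa(community_distance(cnt, "bray_curtis")), cnt2)
  expect_gt(L2["marker", 1], 0)
})

test_that("driving taxa are the top-|loading| union across the first two axes", {
  L <- cbind(Axis1 = c(5, 4, 3, 2, 1, 0.5, 0.2, 0.1, 0, 0),
             Axis2 = c(0, 0, 0, 0, 6, 5, 4, 3, 2, 1))
  rownames(L) <- paste0("t", 1:10)
  # no overlap: 4 + 4 = 8 unique taxa
  expect_equal(driving_taxa(L), c("t1", "t2", "t3", "t4", "t5", "t6", "t7", "t8"))

  # full overlap collapses to 4
  L2 <- cbind(Axis1 = c(4, 3, 2, 1, 0, 0), Axis2 = c(8, 6, 4, 2, 1, 0))
  rownames(L2) <- paste0("t", 1:6)
  expect_equal(driving_taxa(L2), c("t1", "t2", "t3", "t4"))

  # sign is irrelevant; ties break by label
  L3 <- cbind(Axis1 = c(-5, 5, 2, 2, 1), Axis2 = c(0, 0, 0, 0, 1))
  rownames(L3) <- c("b", "a", "d", "c", "e")
  expect_equal(driving_taxa(L3, n_axes = 1, top_k = 4), c("a", "b", "c", "d"))

  expect_warning(out <- driving_taxa(L3[1:3, , drop = FALSE], top_k = 4),
                 "fewer taxa")
  expect_equal(sort(out), sort(c("b", "a", "d")))
})

test_that("block-structured communities yield their block markers as driving taxa", {
  # two sample blocks dominated by distinct taxon blocks
  set.seed(21)
  base <- matrix(rpois(20 * 12, 5), 20, 12)
  blockA <- 1:3; blockB <- 4:6
  base[blockA, 1:6] <- base[blockA, 1:6] + 80
  base[blockB, 7:12] <- base[blockB, 7:12] + 80
  dimnames(base) <- list(paste0("t", 1:20), paste0("s", 1:12))
  ord <- pcoa(community_distance(tss_normalize(base), "bray_curtis"))
  L <- taxon_loadings(ord, base, n_axes = 2)
  dt <- driving_taxa(L, top_k = 3)
  # the first axis separates the two sample blocks, so its top loadings
  # are the block-defining taxa
  top_axis1 <- rownames(L)[order(-abs(L[, 1]))][1:3]
  expect_true(all(top_axis1 %in% paste0("t", c(blockA, blockB))))
  expect_gte(sum(paste0("t", c(blockA, blockB)) %in% dt), 3)
})
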