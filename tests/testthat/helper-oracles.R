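# Independent brute-force oracles shared by the module and acceptance tests.
# Each is written as a direct transcription of the defining formulas, without
# reference to the package implementation.

# Co-occurrence SES oracle: explicit-loop correlations against the documented
# null protocol (per replicate, a uniform draw per cell; row i permuted by
# order(U[i, ]); tail counts with the 1e-9 tolerance).
cooc_oracle <- function(counts, n_null, seed, kind = "spearman") {
  X <- counts
  if (kind == "spearman") X <- t(apply(X, 1, rank))
  n <- nrow(X); m <- ncol(X)
  corr <- function(a, b) {
    am <- a - mean(a); bm <- b - mean(b)
    sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
  }
  obs <- matrix(NA_real_, n, n)
  for (i in 1:n) for (j in 1:n) if (i != j) obs[i, j] <- corr(X[i, ], X[j, ])
  s1 <- s2 <- matrix(0, n, n); ge <- le <- matrix(0, n, n)
  set.seed(seed)
  for (b in seq_len(n_null)) {
    U <- matrix(runif(n * m), n, m)
    Xp <- X
    for (i in 1:n) Xp[i, ] <- X[i, order(U[i, ])]
    for (i in 1:n) for (j in 1:n) if (i != j) {
      cc <- corr(Xp[i, ], Xp[j, ])
      s1[i, j] <- s1[i, j] + cc
      s2[i, j] <- s2[i, j] + cc^2
      ge[i, j] <- ge[i, j] + (cc >= obs[i, j] - 1e-9)
      le[i, j] <- le[i, j] + (cc <= obs[i, j] + 1e-9)
    }
  }
  mu <- s1 / n_null
  sdv <- sqrt(pmax(s2 / n_null - mu^2, 0) * n_null / (n_null - 1))
  score <- (obs - mu) / sdv
  p <- pmin(2 * pmin((ge + 1) / (n_null + 1), (le + 1) / (n_null + 1)), 1)
  diag(p) <- NA
  list(score = score, p = p)
}

# PERMANOVA oracle for one categorical factor: sums of squares straight from
# the pairwise distance matrix, p by scanning a supplied permutation set.
perm_oracle <- function(d, g, perms) {
  D2 <- as.matrix(d)^2
  n <- nrow(D2)
  ss_total <- sum(D2[upper.tri(D2)]) / n
  ss_within <- function(gg) {
    sum(vapply(unique(gg), function(lv) {
      idx <- which(gg == lv)
      sum(D2[idx, idx][upper.tri(D2[idx, idx])]) / length(idx)
    }, numeric(1)))
  }
  a <- length(unique(g))
  f_of <- function(gg) {
    ssw <- ss_within(gg)
    ((ss_total - ssw) / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_of(g)
  f_perm <- apply(perms, 1, function(ix) f_of(g[ix]))
  list(F = f_obs, r2 = (ss_total - ss_within(g)) / ss_total,
       p = (sum(f_perm >= f_obs - 1e-12) + 1) / (nrow(perms) + 1))
}

# complete enumeration of the permutations of 1:n (n! rows)
all_perms <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

# Newton-Raphson oracle for the Poisson log-link MLE with optional offset
newton_poisson <- function(X, y, offset = NULL, tol = 1e-12) {
  if (is.null(offset)) offset <- rep(0, length(y))
  beta <- rep(0, ncol(X))
  for (it in 1:100) {
    eta <- drop(X %*% beta) + offset
    mu <- exp(eta)
    grad <- drop(crossprod(X, y - mu))
    H <- crossprod(X, X * mu)
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}
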