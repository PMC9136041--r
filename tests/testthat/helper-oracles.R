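# Independent oracles used across the suite.  Each reimplements a
# quantity by the most transparent route available (brute-force
# counting, closed forms, exhaustive sums) so the package code is
# checked against something it does not share a code path with.

# Tie-aware pairwise AUC: P(pos > neg) + 0.5 P(pos == neg).
pairwise_auc <- function(pos, neg) {
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Closed-form single-component PLS1 on centered X, centered y:
# w proportional to X'y (unit norm), t = Xw, loading p = X't / t't.
pls1_oracle <- function(x, y) {
  w <- unname(drop(crossprod(x, y)))
  w <- w / sqrt(sum(w^2))
  t <- unname(drop(x %*% w))
  p <- unname(drop(crossprod(x, t))) / sum(t^2)
  list(w = w, t = t, p = p)
}

# Brute-force hypergeometric upper tail from exact binomial
# coefficients, no logs.
brute_hyper_tail <- function(N, K, n, k) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Eigen-decomposition PCA oracle (covariance route, not SVD).
eigen_pca_oracle <- function(x, k) {
  xc <- sweep(x, 2, colMeans(x), "-")
  eg <- eigen(stats::cov(xc), symmetric = TRUE)
  list(loadings = eg$vectors[, seq_len(k), drop = FALSE],
       scores = xc %*% eg$vectors[, seq_len(k), drop = FALSE],
       explained = eg$values / sum(eg$values))
}

# Align the column signs of b to a before comparison.
sign_align <- function(a, b) {
  for (j in seq_len(ncol(a))) {
    if (sum(a[, j] * b[, j]) < 0) b[, j] <- -b[, j]
  }
  b
}

random_matrix <- function(n, p, seed, positive = FALSE) {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("S%02d", 1:n), sprintf("M%02d", 1:p)))
  if (positive) m <- 2^(m + 10)
  m
}
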