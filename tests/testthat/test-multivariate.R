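# PCA and OPLS-DA against independent oracles, plus their algebraic
# invariants.

test_that("PCA recovers a rank-1 matrix in one component", {
  set.seed(1)
  u <- rnorm(10)
  v <- rnorm(4)
  m <- outer(u, v)
  colnames(m) <- paste0("M", 1:4)
  fit <- pca(m, n_components = 3)
  expect_equal(unname(fit$explained_variance[1]), 1, tolerance = 1e-10)
})

test_that("PCA agrees with an eigen-decomposition oracle up to column sign", {
  for (seed in 1:5) {
    m <- random_matrix(12, 6, seed = seed)
    fit <- pca(m, n_components = 4)
    orc <- eigen_pca_oracle(m, 4)
    expect_equal(sign_align(fit$loadings, orc$loadings),
                 fit$loadings, tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(sign_align(fit$scores, orc$scores),
                 fit$scores, tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(unname(fit$explained_variance),
                 orc$explained[1:4], tolerance = 1e-8)
  }
})

test_that("full-rank PCA reconstructs the centered matrix; variance fractions are monotone", {
  m <- random_matrix(12, 6, seed = 31)
  fit <- pca(m, n_components = 6)
  xc <- sweep(m, 2, colMeans(m), "-")
  expect_equal(fit$scores %*% t(fit$loadings), xc, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(fit$explained_variance) <= 1e-12))
  expect_lte(sum(fit$explained_variance), 1 + 1e-8)
  expect_lt(max(abs(crossprod(fit$loadings) - diag(6))), 1e-8)
})

test_that("PCA rejects too many components and separates well-split groups", {
  m <- random_matrix(12, 6, seed = 2)
  expect_error(pca(m, n_components = 7), "n_components")
  # two groups spiked apart on every metabolite: PC1 splits them by sign
  set.seed(8)
  g <- rep(c("A", "B"), each = 10)
  m2 <- matrix(rnorm(20 * 5), 20, 5, dimnames = list(NULL, paste0("M", 1:5)))
  m2[g == "B", ] <- m2[g == "B", ] + 6
  fit <- pca(uv_scale(m2), n_components = 2)
  expect_true(sign(mean(fit$scores[g == "A", 1])) !=
              sign(mean(fit$scores[g == "B", 1])))
})

test_that("OPLS-DA with no orthogonal component reduces to textbook PLS1", {
  for (seed in 1:3) {
    x <- random_matrix(10, 5, seed = seed)
    x <- sweep(x, 2, colMeans(x), "-")
    labels <- rep(c("A", "B"), each = 5)
    y <- ifelse(labels == "B", 1, -1)
    fit <- oplsda(x, labels, n_ortho = 0, cv_folds = 2, seed = 1)
    orc <- pls1_oracle(x, y - mean(y))
    # orientation: package orients t toward the later group
    flip <- if (mean(orc$t[labels == "B"]) < 0) -1 else 1
    expect_equal(unname(fit$weights), flip * orc$w, tolerance = 1e-8)
    expect_equal(unname(fit$predictive_scores), flip * orc$t,
                 tolerance = 1e-8)
    expect_equal(unname(fit$loadings), flip * orc$p, tolerance = 1e-8)
  }
})

test_that("the only informative metabolite attains the maximum VIP", {
  set.seed(12)
  labels <- rep(c("A", "B"), each = 20)
  x <- matrix(rnorm(40 * 30), 40, 30, dimnames = list(NULL, paste0("M", 1:30)))
  x[labels == "B", 1] <- x[labels == "B", 1] + 2
  fit <- oplsda(log2_center(2^(x + 10)), labels)
  expect_identical(names(which.max(fit$vip)), "M1")
  expect_gt(fit$vip["M1"], 1)
})

test_that("every fit satisfies mean(VIP^2) = 1, |pcorr| <= 1, and t ⟂ t_ortho", {
  for (seed in 1:4) {
    n_ortho <- seed %% 3   # 1, 2, 0, 1
    x <- random_matrix(16, 8, seed = 100 + seed)
    labels <- rep(c("A", "B"), each = 8)
    fit <- oplsda(sweep(x, 2, colMeans(x), "-"), labels,
                  n_ortho = n_ortho, cv_folds = 4, seed = 1)
    expect_equal(mean(fit$vip^2), 1, tolerance = 1e-8)
    expect_true(all(abs(fit$splot$pcorr) <= 1))
    for (j in seq_len(ncol(fit$orthogonal_scores))) {
      expect_lt(abs(sum(fit$predictive_scores *
                        fit$orthogonal_scores[, j])), 1e-8)
    }
    # orientation convention: group "B" has positive mean score
    expect_gt(mean(fit$predictive_scores[labels == "B"]), 0)
  }
})

test_that("y-orthogonal structure does not perturb the predictive score", {
  set.seed(44)
  n <- 20
  labels <- rep(c("A", "B"), each = n / 2)
  y <- scale(ifelse(labels == "B", 1, -1), scale = FALSE)
  a <- rnorm(12)
  base <- y %*% t(a) + matrix(rnorm(n * 12, sd = 1e-6), n, 12)
  colnames(base) <- paste0("M", 1:12)
  z <- rnorm(n)
  z <- z - mean(z)
  z <- z - drop(crossprod(z, y) / crossprod(y)) * y   # z ⟂ y
  q <- rnorm(12)
  contaminated <- base + 3 * z %*% t(q)
  t0 <- oplsda(base, labels, n_ortho = 0, cv_folds = 4)$predictive_scores
  t1 <- oplsda(contaminated, labels, n_ortho = 1,
               cv_folds = 4)$predictive_scores
  expect_gt(abs(cor(t0, t1)), 1 - 1e-6)
})

test_that("contract errors: one class, short classes, bad labels length", {
  x <- random_matrix(10, 4, seed = 9)
  expect_error(oplsda(x, rep("A", 10)), "two classes")
  expect_error(oplsda(x, c(rep("A", 8), "B", "B")), ">= 3")
  expect_error(oplsda(x, rep("A", 3)), "labels length|two classes")
})

test_that("permutation test calibrates on null data and nails planted signal", {
  # planted signal: every metabolite shifted -> observed Q2 beats all
  # 99 permutations, p = 1/100
  set.seed(77)
  labels <- rep(c("A", "B"), each = 10)
  x <- matrix(rnorm(20 * 10), 20, 10, dimnames = list(NULL, paste0("M", 1:10)))
  x[labels == "B", ] <- x[labels == "B", ] + 4
  x <- sweep(x, 2, colMeans(x), "-")
  res <- permutation_test(x, labels, n_perm = 99, seed = 5)
  expect_equal(res$p_value, 0.01)
  expect_length(res$permuted_q2, 99)

  # determinism and invariance to label encoding
  res2 <- permutation_test(x, labels, n_perm = 99, seed = 5)
  expect_identical(res$p_value, res2$p_value)
  swapped <- ifelse(labels == "A", "B", "A")
  res3 <- permutation_test(x, swapped, n_perm = 99, seed = 5)
  expect_equal(res3$p_value, res$p_value)

  # null: labels independent of data; p rarely small
  small_p <- 0
  for (seed in 1:5) {
    xn <- random_matrix(16, 8, seed = 200 + seed)
    pn <- permutation_test(sweep(xn, 2, colMeans(xn), "-"),
                           rep(c("A", "B"), each = 8),
                           n_perm = 49, seed = seed)$p_value
    small_p <- small_p + (pn <= 0.05)
  }
  expect_lte(small_p, 1)
})
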