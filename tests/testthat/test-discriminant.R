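# Linear score panels, ROC/AUC/Youden, and the penalized logistic fit.

test_that("linear scores are plain weighted sums over the panel terms", {
  panel <- reference_panel("IPBS_vs_PST")
  expect_identical(panel$comparison, c("IPBS", "PST"))
  sample <- setNames(rep(0, 5), panel$terms$metabolite_id)
  sample["anserine"] <- 100000
  expect_equal(linear_score(panel, sample), 0.7)
  expect_equal(linear_score(panel, setNames(rep(0, 5),
                                            panel$terms$metabolite_id)), 0)

  # random 5-term model against an explicit accumulation
  set.seed(2)
  mdl <- structure(list(terms = data.frame(
    metabolite_id = paste0("m", 1:5), weight = rnorm(5))),
    class = "discriminant_model")
  x <- setNames(runif(8, 0, 1e5), paste0("m", 1:8))
  acc <- 0
  for (i in 1:5) acc <- acc + mdl$terms$weight[i] * x[[paste0("m", i)]]
  expect_equal(linear_score(mdl, x), acc, tolerance = 1e-12)

  expect_error(linear_score(mdl, x[1:4]), "m5")
})

test_that("all three bundled panels load with their fixed coefficients", {
  panels <- reference_panels()
  expect_setequal(names(panels),
                  c("IPBS_vs_PST", "IPBS_vs_PQS", "IPBS_vs_PQD"))
  expect_equal(nrow(panels$IPBS_vs_PST$terms), 5)
  expect_equal(nrow(panels$IPBS_vs_PQS$terms), 4)
  expect_equal(nrow(panels$IPBS_vs_PQD$terms), 6)
  w <- panels$IPBS_vs_PQS$terms
  expect_equal(w$weight[w$metabolite_id == "cytidine 5'-diphosphocholine"],
               0.000017)
})

test_that("ROC curves match brute-force pairwise counting, with and without ties", {
  # perfectly separated
  r <- roc_curve(c(1, 2, 8, 9), c("n", "n", "p", "p"), positive = "p")
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)

  # interleaved: negatives {2,4}, positives {3,5} -> 0.75
  r2 <- roc_curve(c(2, 4, 3, 5), c("n", "n", "p", "p"), positive = "p")
  expect_equal(r2$auc, 0.75)

  # tie-aware: negatives {1,2}, positives {2,3} -> 0.875
  r3 <- roc_curve(c(1, 2, 2, 3), c("n", "n", "p", "p"), positive = "p")
  expect_equal(r3$auc, 0.875)

  # curve endpoints and monotonicity
  expect_equal(r3$tpr[1], 0)
  expect_equal(r3$fpr[1], 0)
  expect_equal(tail(r3$tpr, 1), 1)
  expect_equal(tail(r3$fpr, 1), 1)
  expect_true(all(diff(r3$tpr) >= 0) && all(diff(r3$fpr) >= 0))

  expect_error(roc_curve(1:4, rep("p", 4)), "two classes")
})

test_that("AUC invariants: pairwise identity, monotone transforms, label swap", {
  set.seed(6)
  for (rep in 1:25) {
    n_pos <- sample(2:25, 1)
    n_neg <- sample(2:25, 1)
    # discrete support forces ties
    scores <- sample(1:10, n_pos + n_neg, replace = TRUE)
    labels <- c(rep("pos", n_pos), rep("neg", n_neg))
    suppressWarnings({
      r <- roc_curve(scores, labels, positive = "pos")
      expect_equal(r$auc, pairwise_auc(scores[labels == "pos"],
                                       scores[labels == "neg"]),
                   tolerance = 1e-12)
      # strictly increasing transform leaves the AUC unchanged
      r_t <- roc_curve(exp(scores / 3), labels, positive = "pos")
      expect_equal(r_t$auc, r$auc, tolerance = 1e-12)
      # swapping the positive class mirrors the AUC
      r_sw <- roc_curve(scores, labels, positive = "neg")
      expect_equal(r_sw$auc, 1 - r$auc, tolerance = 1e-12)
    })
  }
})

test_that("AUC matches pROC on random instances with ties", {
  set.seed(27)
  for (rep in 1:5) {
    scores <- sample(seq(0, 5, 0.5), 40, replace = TRUE)
    labels <- sample(c("n", "p"), 40, replace = TRUE, prob = c(0.6, 0.4))
    if (length(unique(labels)) < 2) next
    suppressWarnings(r <- roc_curve(scores, labels, positive = "p"))
    ref <- suppressMessages(as.numeric(
      pROC::auc(pROC::roc(labels, scores, levels = c("n", "p"),
                          direction = "<"))))
    expect_equal(r$auc, ref, tolerance = 1e-12)
  }
})

test_that("the Youden point maximizes sensitivity + specificity - 1", {
  set.seed(19)
  scores <- round(rnorm(40), 1)
  labels <- rep(c("n", "p"), 20)
  suppressWarnings(r <- roc_curve(scores, labels, positive = "p"))
  pos <- scores[labels == "p"]
  neg <- scores[labels == "n"]
  best <- max(vapply(unique(scores), function(t)
    mean(pos >= t) + mean(neg < t) - 1, 0))
  expect_equal(r$sensitivity + r$specificity - 1, best, tolerance = 1e-12)
  # the reported cutoff actually achieves the reported operating point
  expect_equal(mean(pos >= r$youden_cutoff), r$sensitivity)
  expect_equal(mean(neg < r$youden_cutoff), r$specificity)
})

test_that("a single separable candidate yields a perfect fitted panel", {
  set.seed(30)
  x <- matrix(c(rnorm(10, 5, 0.1), rnorm(10, 50, 0.1)), ncol = 1,
              dimnames = list(NULL, "marker"))
  labels <- rep(c("IPBS", "PST"), each = 10)
  m <- fit_discriminant(x, labels, positive = "PST")
  expect_equal(m$roc$auc, 1)
  expect_identical(m$terms$metabolite_id, "marker")
  expect_gt(m$terms$weight, 0)
  scores <- linear_score(m, x)
  expect_true(all((scores >= m$cutoff) == (labels == "PST")))
})

test_that("the ridge logistic fit agrees with glmnet on a random instance", {
  set.seed(91)
  n <- 300
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("m", 1:4)))
  eta <- x %*% c(1, -0.5, 0.25, 0)
  y <- rbinom(n, 1, plogis(eta))
  mine <- syndromet:::.ridge_logistic(x, y, lambda = 0.01)
  gfit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                         lambda = 0.01, standardize = TRUE,
                         thresh = 1e-12)
  gw <- as.numeric(stats::coef(gfit))[-1]
  expect_equal(mine$weights, gw, tolerance = 0.02, ignore_attr = TRUE)
})

test_that("fitting recovers a known generative weight vector", {
  set.seed(55)
  n <- 500
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("m", 1:3)))
  w_star <- c(1.5, -1, 0.5)
  y01 <- rbinom(n, 1, plogis(x %*% w_star))
  labels <- ifelse(y01 == 1, "PST", "IPBS")
  m <- fit_discriminant(x + 100, labels, positive = "PST", lambda = 1e-4)
  w <- m$terms$weight
  # compare directions after scale alignment
  w_hat <- w / sqrt(sum(w^2))
  w_ref <- w_star / sqrt(sum(w_star^2))
  expect_lt(max(abs(w_hat - w_ref) / abs(w_ref)), 0.15)
})

test_that("pure-noise candidates give chance-level cross-validated AUC", {
  set.seed(61)
  n <- 400
  x <- matrix(rnorm(n * 5, 10), n, 5, dimnames = list(NULL, paste0("m", 1:5)))
  labels <- rep(c("IPBS", "PST"), each = n / 2)
  suppressWarnings(
    cv <- cv_auc(x, labels, positive = "PST", folds = 5, seed = 2))
  expect_gte(cv$auc, 0.4)
  expect_lte(cv$auc, 0.6)
})

test_that("discriminant contract errors", {
  x <- random_matrix(10, 3, seed = 1)
  expect_error(fit_discriminant(x, rep("A", 10)), "two classes")
  expect_error(fit_discriminant(x, rep(c("A", "B"), 5),
                                candidates = "zzz"), "zzz")
  expect_error(fit_discriminant(x, rep(c("A", "B"), 5),
                                candidates = character()), "empty")
})
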