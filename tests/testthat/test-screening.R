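# Fold changes, differential calling, top-k cores, essence set.

test_that("fold changes are group-mean ratios on the raw scale", {
  m <- rbind(c(2, 10), c(2, 10), c(4, 10), c(4, 10))
  colnames(m) <- c("a", "b")
  lab <- c("G1", "G1", "G2", "G2")
  fc <- fold_change(m, lab, "G1", "G2")
  expect_equal(fc, c(a = 2, b = 1))
  expect_equal(log2(fc[["a"]]), 1)

  # identical groups: fold change 1
  m2 <- rbind(m[1:2, ], m[1:2, ])
  expect_equal(unname(fold_change(m2, lab, "G1", "G2")), c(1, 1))

  # random instance against an independent recomputation
  m3 <- random_matrix(20, 7, seed = 3, positive = TRUE)
  lab3 <- rep(c("A", "B"), each = 10)
  fc3 <- fold_change(m3, lab3, "A", "B")
  manual <- apply(m3, 2, function(col)
    mean(col[lab3 == "B"]) / mean(col[lab3 == "A"]))
  expect_equal(fc3, manual, tolerance = 1e-12)

  expect_error(fold_change(m, lab, "G1", "G3"), "empty group: G3")
})

test_that("differential calls use strict inequalities on both axes", {
  vip <- c(m1 = 1.2, m2 = 1.0, m3 = 0.5, m4 = 1.5, m5 = 0.5)
  fc <- c(m1 = 3, m2 = 2, m3 = 1.1, m4 = 1.5, m5 = 0.25)
  calls <- call_differential(vip, fc)
  expect_identical(calls$status,
                   c("differential",    # vip>1 and |log2 3|>1
                     "indeterminate",   # both exactly at threshold
                     "nondifferential", # both strictly inside
                     "indeterminate",   # vip>1 but fc inside band
                     "indeterminate"))  # vip<1 but strong down-regulation
  expect_equal(calls$log2_fc, log2(calls$fold_change), tolerance = 1e-10)

  # one-sided band: strong down-regulation becomes non-differential
  calls1 <- call_differential(vip, fc, symmetric = FALSE)
  expect_identical(calls1$status[5], "nondifferential")

  expect_error(call_differential(vip, fc[1:3]), "lengths differ")
  expect_error(call_differential(vip, fc[c(2, 1, 3, 4, 5)]), "aligned")
})

test_that("differential and non-differential sets are disjoint and threshold-monotone", {
  set.seed(5)
  vip <- runif(200, 0, 2)
  fc <- 2^runif(200, -2, 2)
  names(vip) <- names(fc) <- sprintf("m%03d", 1:200)
  calls <- call_differential(vip, fc)
  expect_equal(
    length(intersect(calls$metabolite_id[calls$status == "differential"],
                     calls$metabolite_id[calls$status == "nondifferential"])),
    0L)
  # a stricter fold-change cutoff never grows the differential set
  strict <- call_differential(vip, fc, log2fc_threshold = 1.5)
  expect_true(all(strict$metabolite_id[strict$status == "differential"] %in%
                  calls$metabolite_id[calls$status == "differential"]))
})

test_that("top-k cores rank by group means with lexicographic ties", {
  # hand-built ranking: group1 m1>m2>m3>m4>m5, group2 m5>m2>m1>m4>m3
  m <- rbind(c(50, 40, 30, 20, 10),
             c(50, 40, 30, 20, 10),
             c(30, 40, 10, 20, 50),
             c(30, 40, 10, 20, 50))
  colnames(m) <- paste0("m", 1:5)
  lab <- c("g1", "g1", "g2", "g2")
  res <- top_k_abundant_core(m, lab, k = 3)
  expect_identical(res$per_group$g1, c("m1", "m2", "m3"))
  expect_identical(res$per_group$g2, c("m5", "m2", "m1"))
  expect_identical(res$core, c("m1", "m2"))

  # identical groups: core has exactly k members
  lab_same <- c("g1", "g2", "g1", "g2")
  m_same <- rbind(m[1, ], m[1, ], m[1, ], m[1, ])
  colnames(m_same) <- paste0("m", 1:5)
  expect_length(top_k_abundant_core(m_same, lab_same, k = 3)$core, 3)

  # k = n_metabolites: core is everything
  expect_length(top_k_abundant_core(m, lab, k = 5)$core, 5)

  # ties broken by metabolite id
  m_tie <- rbind(c(1, 1, 1), c(1, 1, 1))
  colnames(m_tie) <- c("b", "a", "c")
  expect_identical(top_k_abundant_core(m_tie, c("g", "g"), k = 2)$per_group$g,
                   c("a", "b"))

  expect_error(top_k_abundant_core(m, lab, k = 6), "k must be")

  # monotonicity: raising k never shrinks the core
  m4 <- random_matrix(10, 20, seed = 8, positive = TRUE)
  lab4 <- rep(c("x", "y"), each = 5)
  for (k in 2:19) {
    expect_true(all(top_k_abundant_core(m4, lab4, k)$core %in%
                    top_k_abundant_core(m4, lab4, k + 1)$core))
  }
})

test_that("essence set is the intersection of its parent cores", {
  nd <- list(IPBS_vs_PST = c("A", "B", "C"),
             IPBS_vs_PQS = c("B", "C"),
             IPBS_vs_PQD = c("B", "C", "D"))
  res <- essence_set(nd, topk_core = c("B", "D"))
  expect_identical(res$nondiff_core, c("B", "C"))
  expect_identical(res$essence, "B")
  expect_true(all(res$essence %in% res$nondiff_core))
  expect_true(all(res$essence %in% res$topk_core))

  # an empty non-differential set empties the essence set
  nd2 <- nd
  nd2$IPBS_vs_PQS <- character()
  expect_length(essence_set(nd2, c("B", "D"))$essence, 0)

  expect_error(essence_set(nd[1:2], c("B"),
                           required = names(nd)),
               "IPBS_vs_PQD")
})
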