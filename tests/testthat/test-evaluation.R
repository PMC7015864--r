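test_that("positive pairs are exactly the lncRNAs sharing a target", {
  tab <- interaction_table(c("L1", "L2"), c("G1", "G1"), "lncRNA-mRNA")
  expect_equal(build_positive_pairs(tab), pairs_df("L1", "L2"))

  none <- interaction_table(c("L1", "L2"), c("G1", "G2"), "lncRNA-mRNA")
  expect_equal(nrow(build_positive_pairs(none)), 0)

  trio <- interaction_table(c("L1", "L2", "L3"), rep("G1", 3), "lncRNA-mRNA")
  expect_equal(nrow(build_positive_pairs(trio)), 3)  # C(3,2)
})

test_that("negative sampling is uniform over the allowed pool and reproducible", {
  pos <- pairs_df("L1", "L2")
  got <- sample_negative_pairs(c("L1", "L2", "L3"), pos, 2, seed = 9)
  expect_equal(got, pairs_df(c("L1", "L2"), c("L3", "L3")))

  ids <- sprintf("L%02d", 1:12)
  s1 <- sample_negative_pairs(ids, pos, 10, seed = 4)
  s2 <- sample_negative_pairs(ids, pos, 10, seed = 4)
  expect_identical(s1, s2)
  s3 <- sample_negative_pairs(ids, pos, 10, seed = 5)
  expect_false(identical(s1, s3))

  expect_error(sample_negative_pairs(c("L1", "L2", "L3"), pos, 4, seed = 1),
               "only 2 available")
})

test_that("balanced subsets follow the per-network cap and merge duplicates", {
  ids <- c("L1", "L2", "L3", "L4")
  pos <- pairs_df(c("L1", "L1"), c("L2", "L3"))

  # identical networks: merged positives collapse to the cap
  full <- make_net("a", ids, c("L1", "L1", "L2", "L2", "L3"),
                   c("L2", "L3", "L3", "L4", "L4"), c(.9, .8, .2, .1, .3))
  twin <- full; twin$name <- "b"
  lab <- balanced_subset(list(full, twin), pos, ids, seed = 1)
  expect_equal(nrow(lab$positives), 2)

  # fully disjoint coverage: k networks times cap
  na <- make_net("a", c("L1", "L2", "X1"), c("L1", "X1"), c("L2", "L1"),
                 c(.9, .1))
  nb <- make_net("b", c("L1", "L3", "X2"), c("L1", "X2"), c("L3", "L3"),
                 c(.8, .2))
  lab2 <- balanced_subset(list(na, nb), pos, c(ids, "X1", "X2"), seed = 1)
  expect_equal(nrow(lab2$positives), 2)  # cap 1 each, no shared pair

  # overlap of one selected pair: 2 + 2 - 1
  n1 <- make_net("a", ids, c("L1", "L1", "L2", "L3"),
                 c("L2", "L3", "L4", "L4"), c(.9, .8, .1, .05))
  n2 <- make_net("b", ids, c("L1", "L1", "L2", "L2", "L3"),
                 c("L3", "L4", "L3", "L4", "L4"), c(.7, .6, .2, .15, .1))
  pos3 <- pairs_df(c("L1", "L1", "L1", "L2"), c("L2", "L3", "L4", "L3"))
  lab3 <- balanced_subset(list(n1, n2), pos3, ids, seed = 1)
  expect_equal(nrow(lab3$positives), 3)

  none <- make_net("a", ids, "L2", "L4", 0.5)
  expect_error(balanced_subset(list(none), pos, ids, seed = 1),
               "no positive pair")
})

roc_from <- function(pos, neg) {
  n <- length(pos) + length(neg)
  ids <- sprintf("P%03d", seq_len(n + 1))
  a <- ids[seq_len(n)]
  b <- rep(ids[n + 1], n)
  net <- make_net("x", ids, a, b, c(pos, neg))
  labels <- labeled_pair_set(pairs_df(a[seq_along(pos)], b[seq_along(pos)]),
                             pairs_df(a[length(pos) + seq_along(neg)],
                                      b[length(pos) + seq_along(neg)]))
  roc_auc(net, labels)
}

test_that("AUC matches hand-counted concordance including ties", {
  expect_equal(roc_from(c(0.9, 0.8), c(0.7, 0.1))$auc, 1)
  expect_equal(roc_from(c(0.9, 0.4), c(0.6, 0.1))$auc, 0.75)
  expect_equal(roc_from(0.5, 0.5)$auc, 0.5)
})

test_that("the ROC curve runs (0,0) to (1,1) and its trapezoid equals the AUC", {
  set.seed(61)
  for (rep in 1:25) {
    pos <- sample(seq(0, 1, by = 0.1), sample(3:20, 1), replace = TRUE)
    neg <- sample(seq(0, 1, by = 0.1), sample(3:20, 1), replace = TRUE)
    r <- roc_from(pos, neg)
    cv <- r$curve
    expect_equal(cv$fpr[1], 0); expect_equal(cv$tpr[1], 0)
    expect_equal(cv$fpr[nrow(cv)], 1); expect_equal(cv$tpr[nrow(cv)], 1)
    expect_true(all(diff(cv$fpr) >= 0) && all(diff(cv$tpr) >= 0))
    trap <- sum(diff(cv$fpr) * (head(cv$tpr, -1) + tail(cv$tpr, -1)) / 2)
    expect_equal(trap, r$auc, tolerance = 1e-12)
    expect_equal(r$auc, oracle_auc(pos, neg), tolerance = 1e-12)
  }
})

test_that("label flips and monotone score transforms behave as AUC theory says", {
  set.seed(71)
  pos <- runif(15); neg <- runif(12)
  base <- roc_from(pos, neg)$auc
  expect_equal(roc_from(neg, pos)$auc, 1 - base, tolerance = 1e-12)
  expect_equal(roc_from(exp(3 * pos), exp(3 * neg))$auc, base,
               tolerance = 1e-12)
})

test_that("per-network weights are each layer's own AUC", {
  ids <- sprintf("L%d", 1:5)
  perfect <- make_net("good", ids, rep("L1", 4), ids[-1],
                      c(0.9, 0.8, 0.2, 0.1))
  anti <- make_net("bad", ids, rep("L1", 4), ids[-1],
                   c(0.1, 0.2, 0.8, 0.9))
  labels <- labeled_pair_set(pairs_df(c("L1", "L1"), c("L2", "L3")),
                             pairs_df(c("L1", "L1"), c("L4", "L5")))
  w <- network_weights(list(perfect, anti), list(labels, labels))
  expect_equal(w, c(good = 1, bad = 0))
})

test_that("rank-sum test separates classes as expected", {
  ids <- sprintf("L%03d", 1:41)
  mk <- function(pos, neg) {
    n <- length(pos) + length(neg)
    a <- ids[seq_len(n)]; b <- rep(ids[41], n)
    list(net = make_net("x", ids, a, b, c(pos, neg)),
         lab = labeled_pair_set(
           pairs_df(a[seq_along(pos)], b[seq_along(pos)]),
           pairs_df(a[length(pos) + seq_along(neg)],
                    b[length(pos) + seq_along(neg)])))
  }
  eq <- mk(c(1, 2, 3), c(1, 2, 3))
  expect_gt(score_distribution_test(eq$net, eq$lab)$p_value, 0.9)

  sep <- mk(seq(2, 3, length.out = 20), seq(0, 1, length.out = 20))
  out <- score_distribution_test(sep$net, sep$lab)
  expect_lt(out$p_value, 0.001)
  expect_equal(unname(out$quartiles["positive", "50%"]), median(sep$net$scores$score[1:20]))

  tiny <- mk(0.9, 0.1)
  expect_gte(score_distribution_test(tiny$net, tiny$lab)$p_value, 0.33)
})

test_that("the evaluation driver is reproducible under a fixed seed", {
  p <- default_pipeline()
  ev1 <- suppressMessages(
    evaluate_networks(p$networks, p$bundle$lnc_mrna, seed = 3))
  ev2 <- suppressMessages(
    evaluate_networks(p$networks, p$bundle$lnc_mrna, seed = 3))
  expect_identical(ev1$weights, ev2$weights)
  expect_identical(ev1$labels, ev2$labels)
  expect_identical(ev1$integrated_roc$auc, ev2$integrated_roc$auc)
  expect_true(all(ev1$weights >= 0 & ev1$weights <= 1))
})
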