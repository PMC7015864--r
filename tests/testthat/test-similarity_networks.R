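test_that("cosine similarity handles orthogonal, proportional, and mixed vectors", {
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(2, 2), c(1, 1)), 1)
  expect_equal(cosine_similarity(c(1, 0.5), c(0.5, 1)), 0.8)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)),
               class = "hetlncsim_undefined_similarity")
  expect_error(cosine_similarity(c(a = 1), c(b = 1)), "key lists")
})

worked_mirna_inputs <- function() {
  # two lncRNAs with partner sets {m1, m2} and {m2, m3}
  tab <- interaction_table(c("L1", "L1", "L2", "L2"),
                           c("m1", "m2", "m2", "m3"), "lncRNA-miRNA")
  misim <- matrix(c(1, 0.4, 0.2,
                    0.4, 1, 0.6,
                    0.2, 0.6, 1), 3, 3,
                  dimnames = list(c("m1", "m2", "m3"), c("m1", "m2", "m3")))
  list(tab = tab, misim = misim)
}

test_that("miRNA vectors follow the max-replacement rule over the union", {
  w <- worked_mirna_inputs()
  fv <- mirna_feature_vectors("L1", "L2", w$tab, w$misim)
  expect_equal(fv$keys, c("m1", "m2", "m3"))
  expect_equal(unname(fv$v1), c(1, 1, 0.6))   # own partners score 1
  expect_equal(unname(fv$v2), c(0.4, 1, 1))
  expect_equal(cosine_similarity(fv$v1, fv$v2),
               2.0 / (sqrt(2.36) * sqrt(2.16)))

  # identical partner sets give identical all-ones vectors
  tab2 <- interaction_table(c("La", "Lb"), c("m1", "m1"), "lncRNA-miRNA")
  fv2 <- mirna_feature_vectors("La", "Lb", tab2, w$misim)
  expect_equal(unname(fv2$v1), 1)
  expect_equal(cosine_similarity(fv2$v1, fv2$v2), 1)
})

test_that("miRNA network scores all covered pairs; worked score appears", {
  w <- worked_mirna_inputs()
  tab3 <- interaction_table(c("L1", "L1", "L2", "L2", "L3"),
                            c("m1", "m2", "m2", "m3", "m1"), "lncRNA-miRNA")
  net <- mirna_network(tab3, w$misim)
  expect_equal(nrow(net$scores), 3)  # C(3,2)
  got <- net$scores$score[net$scores$lncA == "L1" & net$scores$lncB == "L2"]
  expect_equal(got, 2.0 / (sqrt(2.36) * sqrt(2.16)), tolerance = 1e-9)
  expect_equal(round(got, 4), 0.8858)
})

test_that("identity similarity matrix reduces the miRNA layer to binary cosine", {
  set.seed(11)
  mirs <- sprintf("m%02d", 1:12)
  eye <- diag(1, 12)
  dimnames(eye) <- list(mirs, mirs)
  for (rep in 1:20) {
    a <- sample(mirs, sample(1:8, 1))
    b <- sample(mirs, sample(1:8, 1))
    tab <- interaction_table(c(rep("La", length(a)), rep("Lb", length(b))),
                             c(a, b), "lncRNA-miRNA")
    net <- mirna_network(tab, eye)
    want <- length(intersect(a, b)) / sqrt(length(unique(a)) *
                                             length(unique(b)))
    if (want == 0) {
      # orthogonal indicator vectors
      expect_equal(net$scores$score, 0)
    } else {
      expect_equal(net$scores$score, want)
    }
  }
})

sibling_setup <- function() {
  dag <- sibling_dag()
  ds <- disease_similarity_matrix(dag, ids = c("d1", "d2"))
  assoc <- interaction_table(c("L1", "L2"), c("d1", "d2"), "lncRNA-disease")
  list(dag = dag, ds = ds, assoc = assoc)
}

test_that("disease vectors: ds-max blends via DS, dv-literal keeps DV indicators", {
  s <- sibling_setup()
  v1 <- disease_feature_vector("L1", s$assoc, c("d1", "d2"), s$ds, "ds-max")
  expect_equal(unname(v1), c(1, 1 / 3))
  v2 <- disease_feature_vector("L2", s$assoc, c("d1", "d2"), s$ds, "ds-max")
  expect_equal(cosine_similarity(v1, v2), 0.6)  # (2/3) / (10/9)

  l1 <- disease_feature_vector("L1", s$assoc, c("d1", "d2"), s$ds,
                               "dv-literal")
  l2 <- disease_feature_vector("L2", s$assoc, c("d1", "d2"), s$ds,
                               "dv-literal")
  expect_equal(unname(l1), c(1.5, 0))
  expect_equal(cosine_similarity(l1, l2), 0)
})

test_that("disease network mirrors the vector modes", {
  s <- sibling_setup()
  net <- suppressMessages(disease_network(s$assoc, s$ds, "ds-max"))
  expect_equal(net$scores$score, 0.6)
  net_lit <- suppressMessages(disease_network(s$assoc, s$ds, "dv-literal"))
  expect_equal(net_lit$scores$score, 0)

  # identical disease sets score 1 in both modes
  same <- interaction_table(c("L1", "L2"), c("d1", "d1"), "lncRNA-disease")
  expect_equal(suppressMessages(
    disease_network(same, s$ds, "ds-max"))$scores$score, 1)
  expect_equal(suppressMessages(
    disease_network(same, s$ds, "dv-literal"))$scores$score, 1)
})

test_that("spearman similarity matches hand-ranked cases and skips degenerate input", {
  expect_equal(spearman_similarity(c(1, 2, 3), c(10, 20, 30)), 1)
  expect_equal(spearman_similarity(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(spearman_similarity(c(1, 2, 2, 4), c(1, 2, 3, 4)),
               4.5 / sqrt(4.5 * 5), tolerance = 1e-9)
  expect_error(spearman_similarity(c(1, 1, 1), c(1, 2, 3)),
               class = "hetlncsim_undefined_similarity")
  expect_error(spearman_similarity(c(1, 2, NA), c(1, 2, 3)),
               class = "hetlncsim_undefined_similarity")
})

test_that("spearman is invariant under strictly increasing transforms", {
  set.seed(5)
  for (rep in 1:10) {
    x <- runif(15)
    y <- runif(15)
    base <- spearman_similarity(x, y)
    expect_equal(spearman_similarity(log1p(x), y), base)
    expect_equal(spearman_similarity(x, exp(y)), base)
  }
})

test_that("expression network scores all pairs, clamping negatives on request", {
  m <- rbind(L1 = c(1, 2, 3, 4), L2 = c(1.1, 2.1, 3.1, 4.1),
             L3 = c(4, 3, 2, 1))
  colnames(m) <- paste0("t", 1:4)
  net <- suppressMessages(expression_network(m, "demo"))
  expect_equal(nrow(net$scores), 3)
  expect_equal(net$scores$score[net$scores$lncA == "L1" &
                                  net$scores$lncB == "L2"], 1)
  expect_equal(min(net$scores$score), -1)
  clamped <- suppressMessages(expression_network(m, "demo", "clamp-zero"))
  expect_equal(min(clamped$scores$score), 0)

  # a constant row yields undefined pairs which are omitted, not zeroed
  m2 <- rbind(m, L4 = c(2, 2, 2, 2))
  net2 <- suppressMessages(expression_network(m2, "demo"))
  expect_equal(nrow(net2$scores), 3)
  expect_false("L4" %in% c(net2$scores$lncA, net2$scores$lncB))
})

test_that("cosine layers stay within [0,1] on random non-negative inputs", {
  set.seed(23)
  for (rep in 1:50) {
    v1 <- runif(8)
    v2 <- runif(8)
    s <- cosine_similarity(v1, v2)
    expect_gte(s, 0)
    expect_lte(s, 1 + 1e-12)
  }
})
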