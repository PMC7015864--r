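# Validation protocol: lncRNA pairs sharing a target mRNA are the positive
# class, sampled non-sharing pairs the negative class; each layer's ROC AUC
# on this task becomes its fusion weight, and a balanced multi-layer subset
# benchmarks the integrated network.

#' Construct a labeled pair set
#'
#' @param positives,negatives Data frames with columns `lncA`, `lncB`
#'   (unordered pairs; canonicalized here). The two sets must be disjoint.
#' @param seed Integer seed recorded for reproducibility.
#' @return An object of class `labeled_pair_set`.
#' @export
labeled_pair_set <- function(positives, negatives, seed = NA_integer_) {
  positives <- unique_pairs(positives)
  negatives <- unique_pairs(negatives)
  if (length(intersect(pair_key(positives$lncA, positives$lncB),
                       pair_key(negatives$lncA, negatives$lncB))) > 0)
    stop("positive and negative pair sets overlap")
  structure(list(positives = positives, negatives = negatives, seed = seed),
            class = "labeled_pair_set")
}

unique_pairs <- function(df) {
  if (is.null(df) || nrow(df) == 0)
    return(data.frame(lncA = character(), lncB = character(),
                      stringsAsFactors = FALSE))
  if (any(df[[1]] == df[[2]])) stop("pair with duplicated member")
  cp <- canonical_pairs(df[[1]], df[[2]])
  cp <- cp[!duplicated(pair_key(cp$lncA, cp$lncB)), , drop = FALSE]
  cp <- cp[order(cp$lncA, cp$lncB, method = "radix"), , drop = FALSE]
  rownames(cp) <- NULL
  cp
}

#' @export
print.labeled_pair_set <- function(x, ...) {
  cat(sprintf("labeled_pair_set: %d positives, %d negatives (seed %s)\n",
              nrow(x$positives), nrow(x$negatives), x$seed))
  invisible(x)
}

#' Positive pairs: lncRNAs sharing a target mRNA
#'
#' @param lnc_mrna An `interaction_table` of kind `"lncRNA-mRNA"`.
#' @return Data frame `lncA`, `lncB` of all unordered lncRNA pairs with at
#'   least one common target.
#' @export
build_positive_pairs <- function(lnc_mrna) {
  stopifnot(inherits(lnc_mrna, "interaction_table"))
  if (lnc_mrna$kind != "lncRNA-mRNA")
    stop("expected an lncRNA-mRNA interaction table")
  if (nrow(lnc_mrna$pairs) == 0) stop("empty interaction table")
  joined <- merge(lnc_mrna$pairs, lnc_mrna$pairs, by = "partner")
  joined <- joined[joined$lncRNA.x != joined$lncRNA.y, , drop = FALSE]
  unique_pairs(data.frame(joined$lncRNA.x, joined$lncRNA.y))
}

#' Sample negative pairs
#'
#' Draws exactly `count` unordered pairs uniformly without replacement from
#' the pairs over `universe` that are not positives (optionally restricted
#' to a set of allowed pairs, e.g. those scored by one network).
#'
#' @param universe Character vector of lncRNA ids.
#' @param positives Data frame `lncA`, `lncB` of pairs to exclude.
#' @param count Number of pairs to draw.
#' @param seed Integer seed; identical seeds give identical samples.
#' @param within Optional data frame `lncA`, `lncB` restricting candidates.
#' @return Data frame `lncA`, `lncB`.
#' @export
sample_negative_pairs <- function(universe, positives, count, seed,
                                  within = NULL) {
  stopifnot(count > 0)
  universe <- sort(unique(universe), method = "radix")
  if (is.null(within)) {
    if (length(universe) < 2) stop("universe too small")
    idx <- utils::combn(length(universe), 2)
    cand <- data.frame(lncA = universe[idx[1, ]], lncB = universe[idx[2, ]],
                       stringsAsFactors = FALSE)
  } else {
    cand <- unique_pairs(within)
    cand <- cand[cand$lncA %in% universe & cand$lncB %in% universe, ,
                 drop = FALSE]
  }
  pos_keys <- pair_key(canonical_pairs(positives[[1]], positives[[2]])$lncA,
                       canonical_pairs(positives[[1]], positives[[2]])$lncB)
  cand <- cand[!pair_key(cand$lncA, cand$lncB) %in% pos_keys, , drop = FALSE]
  if (nrow(cand) < count)
    stop(sprintf("requested %d negative pairs but only %d available",
                 count, nrow(cand)))
  cand <- cand[order(cand$lncA, cand$lncB, method = "radix"), , drop = FALSE]
  take <- with_substream(seed, 1L, sample.int(nrow(cand), count))
  out <- cand[sort(take), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Balanced multi-layer evaluation subset
#'
#' Mirrors the benchmark construction in which every layer contributes the
#' same number of positive and negative pairs (the minimum positive count
#' over layers), pairs scored in more layers having higher selection
#' priority, and the per-layer selections are merged with duplicates
#' removed.
#'
#' @param networks List of `similarity_network` objects.
#' @param positives Data frame `lncA`, `lncB` of shared-target pairs.
#' @param negatives_universe Character vector of lncRNA ids from which
#'   negatives may be formed (ids with verifiable target sets).
#' @param seed Integer seed, recorded in the result.
#' @return A `labeled_pair_set`.
#' @export
balanced_subset <- function(networks, positives, negatives_universe, seed) {
  stopifnot(length(networks) >= 1)
  positives <- unique_pairs(positives)
  pos_keys <- pair_key(positives$lncA, positives$lncB)
  net_keys <- lapply(networks, function(net)
    pair_key(net$scores$lncA, net$scores$lncB))
  all_keys <- unique(unlist(net_keys, use.names = FALSE))
  mem <- vapply(net_keys, function(k) all_keys %in% k,
                logical(length(all_keys)))
  if (is.null(dim(mem))) mem <- matrix(mem, nrow = length(all_keys))
  n_nets <- rowSums(mem)
  names(n_nets) <- all_keys

  pos_per_net <- lapply(net_keys, function(k) intersect(k, pos_keys))
  counts <- lengths(pos_per_net)
  if (any(counts == 0))
    stop("network scores no positive pair: ",
         vapply(networks, function(n) n$name, "")[counts == 0][1])
  cap <- min(counts)

  pick_top <- function(keys) {
    keys[order(-n_nets[keys], keys, method = "radix")][seq_len(min(cap, length(keys)))]
  }
  sel_pos <- unique(unlist(lapply(pos_per_net, pick_top), use.names = FALSE))

  sel_neg <- unique(unlist(lapply(seq_along(networks), function(i) {
    net <- networks[[i]]
    sc <- net$scores
    ok <- sc$lncA %in% negatives_universe & sc$lncB %in% negatives_universe
    keys <- pair_key(sc$lncA, sc$lncB)[ok]
    keys <- setdiff(keys, pos_keys)
    if (length(keys) == 0)
      stop("network '", net$name, "' scores no candidate negative pair")
    if (length(keys) < cap)
      hl_warn("layer '%s': only %d candidate negatives for cap %d",
              net$name, length(keys), cap)
    pick_top(keys)
  }), use.names = FALSE))

  labeled_pair_set(key_to_pairs(sel_pos), key_to_pairs(sel_neg), seed)
}

key_to_pairs <- function(keys) {
  parts <- strsplit(keys, "\r", fixed = TRUE)
  data.frame(lncA = vapply(parts, `[[`, "", 1L),
             lncB = vapply(parts, `[[`, "", 2L), stringsAsFactors = FALSE)
}

# scores of labeled pairs from a similarity/integrated network or a
# (lncA, lncB, score) data frame; errors if any labeled pair is unscored
labeled_scores <- function(scores, pairs) {
  df <- if (inherits(scores, "similarity_network")) scores$scores
        else if (inherits(scores, "integrated_network")) scores$scores
        else scores
  cp <- canonical_pairs(pairs$lncA, pairs$lncB)
  m <- match(pair_key(cp$lncA, cp$lncB), pair_key(df$lncA, df$lncB))
  if (anyNA(m)) {
    miss <- which(is.na(m))[1]
    stop(sprintf("labeled pair has no score: %s / %s",
                 cp$lncA[miss], cp$lncB[miss]))
  }
  df$score[m]
}

#' ROC curve and AUC for a scored, labeled pair set
#'
#' The AUC uses the rank (Mann-Whitney) formulation, counting tied
#' positive/negative scores as one half; the curve is a threshold sweep
#' over the distinct scores, whose trapezoidal area equals the rank AUC.
#'
#' @param scores A `similarity_network`, `integrated_network`, or data
#'   frame `lncA`, `lncB`, `score`. Every labeled pair must be scored.
#' @param labels A `labeled_pair_set`.
#' @return List of class `roc_result`: `auc`, `curve` (data frame `fpr`,
#'   `tpr` from (0,0) to (1,1)), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(inherits(labels, "labeled_pair_set"))
  pos <- labeled_scores(scores, labels$positives)
  neg <- labeled_scores(scores, labels$negatives)
  roc_from_scores(pos, neg)
}

# core ROC computation on two score vectors
roc_from_scores <- function(pos, neg) {
  n_pos <- length(pos)
  n_neg <- length(neg)
  if (n_pos == 0 || n_neg == 0) stop("need at least one score per class")
  r <- rank(c(pos, neg))
  auc <- (sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thresholds <- sort(unique(c(pos, neg)), decreasing = TRUE)
  tpr <- c(0, vapply(thresholds, function(t) sum(pos >= t), 0) / n_pos)
  fpr <- c(0, vapply(thresholds, function(t) sum(neg >= t), 0) / n_neg)
  structure(list(auc = auc,
                 curve = data.frame(fpr = fpr, tpr = tpr),
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC %.4f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Per-layer AUC weights
#'
#' Evaluates each layer's ROC AUC on its own labeled pairs (restricted to
#' pairs the layer scores); these AUCs are the fusion weights.
#'
#' @param networks List of `similarity_network` objects.
#' @param labels_per_network List of `labeled_pair_set` objects, parallel
#'   to `networks`, each restricted to pairs its network scores.
#' @return Named numeric vector of AUC weights.
#' @export
network_weights <- function(networks, labels_per_network) {
  stopifnot(length(networks) == length(labels_per_network))
  w <- vapply(seq_along(networks), function(i) {
    roc_auc(networks[[i]], labels_per_network[[i]])$auc
  }, 0)
  names(w) <- vapply(networks, function(n) n$name, "")
  w
}

#' Rank-sum comparison of positive vs negative score distributions
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test of the scores of the
#' positive class against the negative class, with per-class quartiles for
#' box-plot-style reporting. Exact enumeration is used for small samples
#' (both classes below 20), the tie-corrected normal approximation
#' otherwise.
#'
#' @param scores As in [roc_auc()].
#' @param labels A `labeled_pair_set`.
#' @return List: `statistic` (rank-sum W), `p_value`, `quartiles` (matrix
#'   with one row per class), `n_pos`, `n_neg`.
#' @export
score_distribution_test <- function(scores, labels) {
  stopifnot(inherits(labels, "labeled_pair_set"))
  pos <- labeled_scores(scores, labels$positives)
  neg <- labeled_scores(scores, labels$negatives)
  if (length(pos) == 0 || length(neg) == 0)
    stop("need at least one score per class")
  exact <- length(pos) < 20 && length(neg) < 20
  ht <- suppressWarnings(stats::wilcox.test(pos, neg, exact = exact,
                                            correct = TRUE,
                                            alternative = "two.sided"))
  q <- rbind(positive = stats::quantile(pos, c(0.25, 0.5, 0.75)),
             negative = stats::quantile(neg, c(0.25, 0.5, 0.75)))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       quartiles = q, n_pos = length(pos), n_neg = length(neg))
}

#' End-to-end evaluation and fusion driver
#'
#' Runs the full validation protocol: derive shared-target positives from
#' the lncRNA-mRNA table; for each layer, pair its scored positives with an
#' equal number of seeded negative pairs (drawn from ids present in the
#' lncRNA-mRNA table and scored by that layer; when fewer non-sharing pairs
#' exist than positives, all of them are used and a warning is logged) and
#' compute its AUC weight;
#' fuse the layers with those weights; evaluate the integrated network on
#' the balanced multi-layer subset.
#'
#' @param networks List of `similarity_network` objects.
#' @param lnc_mrna An `interaction_table` of kind `"lncRNA-mRNA"`.
#' @param seed Integer master seed for all sampling.
#' @param missing,denominator Passed to [integrate_networks()].
#' @return List: `weights`, `per_network` (list of `roc_result`),
#'   `integrated` (the `integrated_network`), `integrated_roc`,
#'   `rank_sum` (from [score_distribution_test()]), `labels` (the balanced
#'   `labeled_pair_set`).
#' @export
evaluate_networks <- function(networks, lnc_mrna, seed,
                              missing = "available", denominator = "n") {
  positives <- build_positive_pairs(lnc_mrna)
  universe <- unique(lnc_mrna$pairs$lncRNA)

  per_network <- vector("list", length(networks))
  w <- numeric(length(networks))
  for (i in seq_along(networks)) {
    net <- networks[[i]]
    scored_keys <- pair_key(net$scores$lncA, net$scores$lncB)
    pos_i <- positives[pair_key(positives$lncA, positives$lncB) %in%
                         scored_keys, , drop = FALSE]
    if (nrow(pos_i) == 0)
      stop("network scores no positive pair: ", net$name)
    universe_i <- intersect(universe, net$coverage)
    in_univ <- net$scores$lncA %in% universe_i & net$scores$lncB %in% universe_i
    n_candidates <- sum(!(pair_key(net$scores$lncA, net$scores$lncB)[in_univ]
                          %in% pair_key(positives$lncA, positives$lncB)))
    n_neg <- min(nrow(pos_i), n_candidates)
    if (n_neg < nrow(pos_i))
      hl_warn("layer '%s': only %d non-sharing pairs available for %d positives",
              net$name, n_neg, nrow(pos_i))
    neg_i <- sample_negative_pairs(
      universe_i, positives, n_neg,
      seed = substream_seed(seed, i),
      within = net$scores[, c("lncA", "lncB")])
    lab_i <- labeled_pair_set(pos_i, neg_i, seed)
    per_network[[i]] <- roc_auc(net, lab_i)
    w[i] <- per_network[[i]]$auc
  }
  names(w) <- vapply(networks, function(n) n$name, "")
  names(per_network) <- names(w)

  integrated <- integrate_networks(networks, w, missing = missing,
                                   denominator = denominator)
  labels <- balanced_subset(networks, positives, universe, seed)
  integrated_roc <- roc_auc(integrated, labels)
  rank_sum <- score_distribution_test(integrated, labels)
  list(weights = w, per_network = per_network, integrated = integrated,
       integrated_roc = integrated_roc, rank_sum = rank_sum, labels = labels)
}
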