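# Builders for the four single-evidence lncRNA similarity layers:
#  - miRNA layer: interaction profiles weighted by a miRNA functional
#    similarity matrix, compared by cosine;
#  - disease layer: Wang-style semantic feature vectors, compared by cosine;
#  - two expression layers: Spearman rank correlation of tissue profiles,
#    computed per atlas (TPM and FPKM atlases are never merged).

undefined_similarity <- function(msg) {
  stop(structure(class = c("hetlncsim_undefined_similarity", "error",
                           "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Cosine similarity of two feature vectors
#'
#' `dot(v1, v2) / (||v1|| * ||v2||)`. For non-negative inputs the result
#' lies in \[0, 1\] and equals 1 for proportional vectors.
#'
#' @param v1,v2 Numeric vectors over the same key list (same length; if
#'   named, names must match).
#' @return A scalar.
#' @export
cosine_similarity <- function(v1, v2) {
  if (length(v1) != length(v2)) stop("feature vectors differ in length")
  if (!is.null(names(v1)) && !is.null(names(v2)) &&
      !identical(names(v1), names(v2)))
    stop("feature vectors have different key lists")
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0)
    undefined_similarity("cosine similarity undefined for zero-norm vector")
  sum(v1 * v2) / (n1 * n2)
}

# similarity of miRNA m to miRNA m2 when either may be absent from the
# matrix: absent pairs contribute 0, except the trivial self-pair.
misim_lookup <- function(misim, from, to) {
  ids <- rownames(misim)
  out <- matrix(0, length(from), length(to), dimnames = list(from, to))
  fi <- from %in% ids
  ti <- to %in% ids
  if (any(fi) && any(ti))
    out[fi, ti] <- misim[from[fi], to[ti], drop = FALSE]
  self <- outer(from, to, "==")
  out[self] <- 1
  out
}

#' miRNA feature vectors for a pair of lncRNAs
#'
#' The two lncRNAs' miRNA partner sets are merged into one ordered union
#' key list. The entry of lncRNA k's vector at miRNA m is the maximum
#' functional similarity between m and any member of k's own partner set —
#' 1 whenever m is itself a partner (unit diagonal), and the best
#' within-matrix surrogate otherwise. With an identity similarity matrix
#' this reduces to the 0/1 membership indicator.
#'
#' @param lnc1,lnc2 lncRNA ids.
#' @param interactions An `interaction_table` of kind `"lncRNA-miRNA"`.
#' @param misim Square miRNA similarity matrix from [read_square_matrix()].
#'   Partner miRNAs absent from it contribute similarity 0 (logged).
#' @return List with elements `v1`, `v2` (named numeric vectors over the
#'   union key list) and `keys`.
#' @export
mirna_feature_vectors <- function(lnc1, lnc2, interactions, misim) {
  sets <- partner_sets(interactions)
  list1 <- sets[[lnc1]]
  list2 <- sets[[lnc2]]
  if (is.null(list1) || length(list1) == 0)
    stop("lncRNA has no miRNA partners: ", lnc1)
  if (is.null(list2) || length(list2) == 0)
    stop("lncRNA has no miRNA partners: ", lnc2)
  keys <- sort(unique(c(list1, list2)), method = "radix")
  absent <- setdiff(keys, rownames(misim))
  if (length(absent) > 0)
    hl_warn("%d miRNAs absent from similarity matrix (contribute 0): %s",
            length(absent), paste(absent, collapse = ", "))
  v1 <- apply(misim_lookup(misim, keys, list1), 1, max)
  v2 <- apply(misim_lookup(misim, keys, list2), 1, max)
  list(v1 = v1, v2 = v2, keys = keys)
}

#' miRNA-based lncRNA similarity network
#'
#' Scores every unordered pair of covered lncRNAs (those with at least one
#' miRNA partner) by the cosine of their miRNA feature vectors.
#'
#' @param interactions An `interaction_table` of kind `"lncRNA-miRNA"`.
#' @param misim Square miRNA similarity matrix.
#' @param name Layer label.
#' @param subset Optional character vector restricting the lncRNAs scored.
#' @return A `similarity_network`.
#' @export
mirna_network <- function(interactions, misim, name = "mirna", subset = NULL) {
  stopifnot(inherits(interactions, "interaction_table"))
  if (interactions$kind != "lncRNA-miRNA")
    stop("expected an lncRNA-miRNA interaction table")
  sets <- partner_sets(interactions)
  coverage <- names(sets)[lengths(sets) > 0]
  if (!is.null(subset)) coverage <- intersect(coverage, subset)
  if (length(coverage) == 0) stop("no lncRNAs with miRNA partners")
  coverage <- sort(coverage, method = "radix")
  score_pairs(coverage, function(a, b) {
    fv <- mirna_feature_vectors(a, b, interactions, misim)
    cosine_similarity(fv$v1, fv$v2)
  }, name = name)
}

#' Disease semantic feature vector of an lncRNA
#'
#' Over a given union key list of diseases, builds the vector representing
#' the lncRNA's disease associations. Mode `"ds-max"` (default) sets the
#' entry at disease d to the maximum semantic similarity between d and any
#' disease associated with the lncRNA, so identical association sets give
#' all-ones vectors. Mode `"dv-literal"` sets the entry to the disease's
#' semantic value `DV(d)` when d is associated and 0 otherwise.
#'
#' @param lnc lncRNA id.
#' @param associations An `interaction_table` of kind `"lncRNA-disease"`.
#' @param union_keys Ordered disease ids spanning the vector.
#' @param ds Disease similarity matrix from [disease_similarity_matrix()].
#' @param mode `"ds-max"` or `"dv-literal"`.
#' @return Named numeric vector over `union_keys`.
#' @export
disease_feature_vector <- function(lnc, associations, union_keys, ds,
                                   mode = c("ds-max", "dv-literal")) {
  mode <- match.arg(mode)
  sets <- partner_sets(associations)
  dl <- intersect(sets[[lnc]], rownames(ds))
  if (length(dl) == 0)
    stop("lncRNA has no associated diseases in the similarity matrix: ", lnc)
  if (mode == "ds-max") {
    v <- apply(ds[union_keys, dl, drop = FALSE], 1, max)
  } else {
    dv <- attr(ds, "semantic_values")
    v <- ifelse(union_keys %in% dl, dv[union_keys], 0)
    names(v) <- union_keys
  }
  v
}

#' Disease-based lncRNA similarity network
#'
#' For each pair of covered lncRNAs (those with at least one associated
#' disease present in the similarity matrix), the union of the two disease
#' sets forms the key list, feature vectors are built per `mode`, and their
#' cosine is the pair's score. Diseases absent from the matrix are dropped
#' with a logged count.
#'
#' @param associations An `interaction_table` of kind `"lncRNA-disease"`.
#' @param ds Disease similarity matrix from [disease_similarity_matrix()].
#' @param mode `"ds-max"` (default) or `"dv-literal"`.
#' @param name Layer label.
#' @param subset Optional character vector restricting the lncRNAs scored.
#' @return A `similarity_network`.
#' @export
disease_network <- function(associations, ds, mode = c("ds-max", "dv-literal"),
                            name = "disease", subset = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(associations, "interaction_table"))
  if (associations$kind != "lncRNA-disease")
    stop("expected an lncRNA-disease association table")
  sets <- partner_sets(associations)
  known <- lapply(sets, intersect, rownames(ds))
  n_dropped <- sum(lengths(sets)) - sum(lengths(known))
  if (n_dropped > 0)
    hl_warn("%d associations to diseases outside the DAG dropped", n_dropped)
  coverage <- names(known)[lengths(known) > 0]
  if (!is.null(subset)) coverage <- intersect(coverage, subset)
  if (length(coverage) == 0)
    stop("no lncRNAs with diseases present in the similarity matrix")
  coverage <- sort(coverage, method = "radix")
  score_pairs(coverage, function(a, b) {
    keys <- sort(unique(c(known[[a]], known[[b]])), method = "radix")
    cosine_similarity(
      disease_feature_vector(a, associations, keys, ds, mode),
      disease_feature_vector(b, associations, keys, ds, mode))
  }, name = name)
}

#' Spearman similarity of two expression profiles
#'
#' Pearson correlation of average-tie fractional ranks over the conditions
#' where both profiles are non-missing. At least three complete conditions
#' are required; a profile that is constant over the complete conditions
#' has no defined rank correlation and raises an undefined-similarity
#' error (callers skip and log the pair).
#'
#' @param p1,p2 Numeric vectors (one value per tissue; `NA` = missing).
#' @return A scalar in \[-1, 1\].
#' @export
spearman_similarity <- function(p1, p2) {
  if (length(p1) != length(p2)) stop("profiles differ in length")
  ok <- !is.na(p1) & !is.na(p2)
  if (sum(ok) < 3)
    undefined_similarity("fewer than 3 pairwise-complete conditions")
  x <- p1[ok]
  y <- p2[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    undefined_similarity("constant profile over complete conditions")
  stats::cor(rank(x), rank(y))
}

#' Expression-based lncRNA similarity network
#'
#' All-pairs Spearman rank correlation of row profiles of one expression
#' atlas. Pairs with undefined correlation (constant profile, too few
#' complete conditions) are omitted from the layer, not scored 0.
#'
#' @param expr Expression matrix from [read_expression_matrix()] (rows =
#'   lncRNAs, columns = tissues).
#' @param name Layer label (e.g. `"GTEx"`, `"NONCODE"`).
#' @param negatives `"keep"` (default) keeps negative correlations;
#'   `"clamp-zero"` floors scores at 0.
#' @param subset Optional character vector restricting the lncRNAs scored.
#' @return A `similarity_network`.
#' @export
expression_network <- function(expr, name, negatives = c("keep", "clamp-zero"),
                               subset = NULL) {
  negatives <- match.arg(negatives)
  if (is.null(dim(expr)) || nrow(expr) == 0) stop("empty expression matrix")
  coverage <- rownames(expr)
  if (!is.null(subset)) coverage <- intersect(coverage, subset)
  if (length(coverage) < 2) stop("need at least 2 lncRNAs")
  coverage <- sort(coverage, method = "radix")
  net <- score_pairs(coverage, function(a, b) {
    spearman_similarity(expr[a, ], expr[b, ])
  }, name = name)
  if (negatives == "clamp-zero") net$scores$score <- pmax(net$scores$score, 0)
  net
}

# Scores all unordered pairs over `coverage` with `score_fun(a, b)`,
# omitting pairs whose score is undefined (logged once with a count).
score_pairs <- function(coverage, score_fun, name) {
  n <- length(coverage)
  if (n < 2) return(similarity_network(name, coverage))
  idx <- utils::combn(n, 2)
  scores <- numeric(ncol(idx))
  keep <- logical(ncol(idx))
  for (k in seq_len(ncol(idx))) {
    a <- coverage[idx[1, k]]
    b <- coverage[idx[2, k]]
    s <- tryCatch(score_fun(a, b),
                  hetlncsim_undefined_similarity = function(e) NA_real_)
    scores[k] <- s
    keep[k] <- !is.na(s)
  }
  if (any(!keep))
    hl_log("layer '%s': %d pairs with undefined similarity omitted",
           name, sum(!keep))
  similarity_network(name, coverage,
                     lncA = coverage[idx[1, keep]],
                     lncB = coverage[idx[2, keep]],
                     score = scores[keep])
}
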