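# Fusion of the single-evidence layers into one integrated similarity:
# a weighted average where each layer's weight is its evaluation AUC.

#' Integrate similarity layers by AUC-weighted averaging
#'
#' For each lncRNA pair, the integrated score is
#' `sum_i AUC_i * S_i / denominator` over the layers that score the pair.
#' The default denominator is the layer count `n`; with
#' `missing = "available"` n counts only the layers scoring that pair,
#' with `missing = "strict"` only pairs scored by every layer are emitted
#' and n is the total layer count. `denominator = "sum-weights"` divides by
#' the summed weights of the contributing layers instead, making the result
#' a convex combination of the contributing scores.
#'
#' @param networks List of `similarity_network` objects with distinct names.
#' @param weights Named numeric vector of per-layer AUC weights in \[0, 1\],
#'   covering every network name (extra names are an error).
#' @param missing `"available"` (default) or `"strict"`.
#' @param denominator `"n"` (default) or `"sum-weights"`.
#' @return An object of class `integrated_network`: list with `scores`
#'   (data frame `lncA`, `lncB`, `score`, `n_networks`), `support` (named
#'   list of contributing layer names per pair), `weights`, and the two
#'   policy choices.
#' @export
integrate_networks <- function(networks, weights,
                               missing = c("available", "strict"),
                               denominator = c("n", "sum-weights")) {
  missing <- match.arg(missing)
  denominator <- match.arg(denominator)
  stopifnot(length(networks) >= 1)
  names(networks) <- vapply(networks, function(n) n$name, "")
  if (anyDuplicated(names(networks))) stop("duplicate network names")
  unknown <- setdiff(names(weights), names(networks))
  if (length(unknown) > 0)
    stop("weight for unknown network: ", paste(unknown, collapse = ", "))
  uncovered <- setdiff(names(networks), names(weights))
  if (length(uncovered) > 0)
    stop("no weight supplied for network: ", paste(uncovered, collapse = ", "))
  if (any(weights < 0 | weights > 1)) stop("weights must lie in [0, 1]")

  long <- do.call(rbind, lapply(networks, function(net) {
    data.frame(net$scores, network = net$name, stringsAsFactors = FALSE)
  }))
  key <- pair_key(long$lncA, long$lncB)
  # deterministic pair order, independent of network input order
  o <- order(key, long$network, method = "radix")
  long <- long[o, , drop = FALSE]
  key <- key[o]
  groups <- split(seq_len(nrow(long)), factor(key, levels = unique(key)))

  n_total <- length(networks)
  rows <- lapply(groups, function(ix) {
    contrib <- long[ix, , drop = FALSE]
    if (missing == "strict" && nrow(contrib) < n_total) return(NULL)
    w <- weights[contrib$network]
    denom <- switch(denominator,
                    "n" = if (missing == "strict") n_total else nrow(contrib),
                    "sum-weights" = sum(w))
    data.frame(lncA = contrib$lncA[1], lncB = contrib$lncB[1],
               score = sum(w * contrib$score) / denom,
               n_networks = nrow(contrib), stringsAsFactors = FALSE)
  })
  keep <- !vapply(rows, is.null, TRUE)
  scores <- if (any(keep)) do.call(rbind, rows[keep]) else
    data.frame(lncA = character(), lncB = character(), score = numeric(),
               n_networks = integer(), stringsAsFactors = FALSE)
  rownames(scores) <- NULL
  support <- lapply(groups[keep], function(ix) long$network[ix])
  names(support) <- pair_key(scores$lncA, scores$lncB)
  structure(list(scores = scores, support = support, weights = weights,
                 missing = missing, denominator = denominator),
            class = "integrated_network")
}

#' @export
print.integrated_network <- function(x, ...) {
  cat(sprintf(
    "integrated_network: %d pairs from %d layers (missing=%s, denominator=%s)\n",
    nrow(x$scores), length(x$weights), x$missing, x$denominator))
  invisible(x)
}

#' Convert an integrated network to a similarity network
#'
#' @param x An `integrated_network`.
#' @param name Layer label for the result.
#' @return A `similarity_network` over the union coverage.
#' @export
as_similarity_network <- function(x, name = "integrated") {
  stopifnot(inherits(x, "integrated_network"))
  similarity_network(name,
                     coverage = unique(c(x$scores$lncA, x$scores$lncB)),
                     lncA = x$scores$lncA, lncB = x$scores$lncB,
                     score = x$scores$score)
}

#' Coverage overlap report across layers
#'
#' Counts, for every non-empty subset of layers, the lncRNAs covered by
#' exactly that subset (the regions of a Venn diagram), plus per-layer
#' totals and the union size.
#'
#' @param networks List of `similarity_network` objects.
#' @return List with `per_layer` (named counts), `union_size`, and
#'   `regions` (data frame `layers`, `count` with `layers` a `+`-joined
#'   subset label).
#' @export
coverage_report <- function(networks) {
  stopifnot(length(networks) >= 1)
  names(networks) <- vapply(networks, function(n) n$name, "")
  covs <- lapply(networks, function(n) n$coverage)
  all_ids <- sort(unique(unlist(covs, use.names = FALSE)), method = "radix")
  membership <- vapply(covs, function(cv) all_ids %in% cv,
                       logical(length(all_ids)))
  if (length(all_ids) == 1) membership <- matrix(membership, nrow = 1)
  labels <- apply(membership, 1, function(row) {
    paste(names(covs)[row], collapse = "+")
  })
  region_counts <- table(labels)
  list(per_layer = vapply(covs, length, 0L),
       union_size = length(all_ids),
       regions = data.frame(layers = names(region_counts),
                            count = as.integer(region_counts),
                            stringsAsFactors = FALSE))
}
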