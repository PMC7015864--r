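# Wang-style semantic similarity over a disease hierarchy DAG: each term's
# ancestors contribute a value that decays by a factor delta per edge on the
# shortest downward path to the term; pairwise similarity compares the
# contribution profiles of two terms over their shared ancestry.

#' Build a disease DAG from a parent/child edge list
#'
#' Verifies acyclicity (one offending cycle is reported on failure) and
#' returns parent/child adjacency maps.
#'
#' @param edges Data frame with columns `parent`, `child`, as returned by
#'   [read_dag_edges()]; or a character matrix with two columns.
#' @return An object of class `disease_dag`: list with `nodes` (character),
#'   `parents` and `children` (named lists of character vectors).
#' @export
disease_dag <- function(edges) {
  parent <- as.character(edges[[1]])
  child <- as.character(edges[[2]])
  if (any(parent == child)) stop("self-loop at node ", parent[parent == child][1])
  nodes <- sort(unique(c(parent, child)), method = "radix")
  g <- igraph::graph_from_data_frame(
    data.frame(from = parent, to = child, stringsAsFactors = FALSE),
    directed = TRUE, vertices = nodes)
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    in_cycle <- names(which(comp$membership == which.max(comp$csize)))
    stop("cycle in disease hierarchy among: ",
         paste(in_cycle, collapse = ", "))
  }
  parents <- split(parent, factor(child, levels = nodes))
  children <- split(child, factor(parent, levels = nodes))
  structure(list(nodes = nodes,
                 parents = lapply(parents, unique),
                 children = lapply(children, unique)),
            class = "disease_dag")
}

#' @export
print.disease_dag <- function(x, ...) {
  n_edges <- sum(lengths(x$children))
  cat(sprintf("disease_dag: %d terms, %d parent-child edges, %d roots\n",
              length(x$nodes), n_edges, sum(lengths(x$parents) == 0)))
  invisible(x)
}

# ancestors of i (excluding i) by upward breadth-first traversal
dag_ancestors <- function(dag, i) {
  seen <- character()
  frontier <- dag$parents[[i]]
  while (length(frontier) > 0) {
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    frontier <- unique(unlist(dag$parents[new], use.names = FALSE))
  }
  seen
}

#' Semantic contributions of a disease's ancestry
#'
#' For anchor term `i`, every term `s` in `T_i` (the anchor plus all its
#' ancestors) contributes `D_i(s)`: 1 for the anchor itself, and otherwise
#' the maximum of `delta * D_i(s')` over the children `s'` of `s` that lie
#' inside `T_i`. Equivalently, `delta` raised to the length of the shortest
#' downward path from `s` to `i`.
#'
#' @param dag A `disease_dag`.
#' @param i Anchor disease id.
#' @param delta Decay factor in (0, 1); 0.5 is the customary value.
#' @return Named numeric vector of contributions over `T_i`, with
#'   attributes `anchor` and `delta`.
#' @export
semantic_contributions <- function(dag, i, delta = 0.5) {
  stopifnot(inherits(dag, "disease_dag"))
  if (!i %in% dag$nodes) stop("unknown disease id: ", i)
  if (!(delta > 0 && delta < 1)) stop("delta must lie strictly in (0, 1)")
  t_i <- c(i, dag_ancestors(dag, i))
  memo <- new.env(parent = emptyenv())
  assign(i, 1, envir = memo)
  contrib <- function(s) {
    if (!is.null(v <- memo[[s]])) return(v)
    kids <- intersect(dag$children[[s]], t_i)
    # every child of s inside T_i is itself the anchor or an ancestor of it
    v <- delta * max(vapply(kids, contrib, 0))
    assign(s, v, envir = memo)
    v
  }
  out <- vapply(t_i, contrib, 0)
  names(out) <- t_i
  attr(out, "anchor") <- i
  attr(out, "delta") <- delta
  out
}

#' Semantic value of a disease
#'
#' The sum of the semantic contributions over the term's ancestry `T_i`;
#' at least 1 since the anchor contributes 1.
#'
#' @param contributions Output of [semantic_contributions()].
#' @return A scalar, `DV(i)`.
#' @export
semantic_value <- function(contributions) {
  sum(contributions)
}

#' Semantic similarity of two diseases
#'
#' `DS(i1, i2)` sums the paired contributions of terms shared by the two
#' ancestries and normalizes by the two semantic values. Equal terms give
#' 1; terms with disjoint ancestries (e.g. in different DAG components)
#' give 0.
#'
#' @param dag A `disease_dag`.
#' @param i1,i2 Disease ids.
#' @param delta Decay factor in (0, 1).
#' @return A scalar in \[0, 1\].
#' @export
disease_similarity <- function(dag, i1, i2, delta = 0.5) {
  c1 <- semantic_contributions(dag, i1, delta)
  c2 <- semantic_contributions(dag, i2, delta)
  ds_from_contribs(c1, c2)
}

ds_from_contribs <- function(c1, c2) {
  shared <- intersect(names(c1), names(c2))
  if (length(shared) == 0) return(0)
  sum(c1[shared] + c2[shared]) / (sum(c1) + sum(c2))
}

#' All-pairs disease semantic similarity matrix
#'
#' Computes each term's contribution table once and assembles the symmetric
#' similarity matrix plus the cached semantic values.
#'
#' @param dag A `disease_dag`.
#' @param ids Disease ids to include (default: all DAG nodes).
#' @param delta Decay factor in (0, 1).
#' @return A symmetric numeric matrix with unit diagonal and attribute
#'   `semantic_values` (named numeric vector of `DV`).
#' @export
disease_similarity_matrix <- function(dag, ids = dag$nodes, delta = 0.5) {
  stopifnot(inherits(dag, "disease_dag"))
  missing_ids <- setdiff(ids, dag$nodes)
  if (length(missing_ids) > 0)
    stop("unknown disease id: ", missing_ids[1])
  tables <- lapply(ids, function(i) semantic_contributions(dag, i, delta))
  names(tables) <- ids
  n <- length(ids)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  if (n > 1) {
    for (a in seq_len(n - 1)) {
      for (b in seq((a + 1), n)) {
        m[a, b] <- m[b, a] <- ds_from_contribs(tables[[a]], tables[[b]])
      }
    }
  }
  attr(m, "semantic_values") <- vapply(tables, semantic_value, 0)
  m
}
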