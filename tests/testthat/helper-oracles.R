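# Independent brute-force oracles and small generators used across tests.

# Enumerates every directed ancestor path (anchor -> ... -> s via parent
# edges) and scores each ancestor as delta^(minimum path edge count).
# Deliberately independent of the memoized implementation.
oracle_contributions <- function(edges, anchor, delta) {
  parents_of <- split(edges$parent, edges$child)
  lens <- new.env(parent = emptyenv())
  walk <- function(node, depth) {
    prev <- lens[[node]]
    if (is.null(prev) || depth < prev) assign(node, depth, envir = lens)
    for (p in parents_of[[node]]) walk(p, depth + 1)
  }
  walk(anchor, 0)
  out <- vapply(ls(lens), function(s) delta^lens[[s]], 0)
  names(out) <- ls(lens)
  out
}

# Exhaustive concordant-pair AUC with ties counted one half.
oracle_auc <- function(pos, neg) {
  grid <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(grid)
}

# Random rooted DAG as a parent/child edge data frame: node j may only
# have parents among nodes 1..j-1, which guarantees acyclicity.
random_dag_edges <- function(n_nodes, p_edge = 0.4, max_parents = 3) {
  edges <- list()
  for (j in 2:n_nodes) {
    k <- sample.int(min(max_parents, j - 1), 1)
    parents <- sample.int(j - 1, k)
    edges[[j]] <- data.frame(parent = sprintf("V%02d", parents),
                             child = sprintf("V%02d", j),
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, edges)
}

# Tiny named DAGs reused in several files.
chain_dag <- function() {
  disease_dag(data.frame(parent = c("C", "B"), child = c("B", "A")))
}
diamond_dag <- function() {
  disease_dag(data.frame(parent = c("R", "R", "P", "Q"),
                         child = c("P", "Q", "A", "A")))
}
sibling_dag <- function() {
  disease_dag(data.frame(parent = c("r", "r"), child = c("d1", "d2")))
}

make_net <- function(name, coverage, lncA, lncB, score) {
  similarity_network(name, coverage, lncA, lncB, score)
}

pairs_df <- function(a, b) data.frame(lncA = a, lncB = b,
                                      stringsAsFactors = FALSE)
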