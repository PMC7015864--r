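# Seeded generator of a complete toy data bundle with planted co-function
# clusters: every cluster owns a pool of miRNAs, sibling-leaf diseases under
# its own DAG branch, target mRNAs, and a mean expression profile per atlas.
# lncRNAs draw partners mostly from their own cluster's pools, so
# same-cluster pairs look similar in all four evidence layers.

#' Fixture generation parameters
#'
#' Defaults describe the standard study conditions: 60 lncRNAs in 3
#' planted clusters, strong within-cluster partner sampling (0.9) with a
#' small cross-cluster leak (0.05), and expression noise at a quarter of
#' the signal scale. Each cluster's diseases sit as sibling leaves under a
#' cluster-specific branch of a shared rooted DAG.
#'
#' @param n_lncRNAs,n_clusters,n_miRNAs,n_diseases,n_mRNAs Entity counts;
#'   pools are split evenly across clusters. The target-mRNA pool is kept
#'   deliberately small (default 6) so that shared-target positive pairs
#'   stay a minority of all pairs, matching the sparsity of real
#'   lncRNA-mRNA interactomes where each lncRNA has only a few validated
#'   targets.
#' @param n_tissues_A,n_tissues_B Tissue counts of the two expression
#'   atlases (TPM and FPKM respectively).
#' @param within_cluster_partner_overlap Probability, in (0, 1\], that an
#'   lncRNA picks up each partner from its own cluster's pool.
#' @param cross_cluster_leak Probability, in \[0, 1), of picking up each
#'   partner from another cluster's pool; must be below the overlap.
#' @param expression_noise_sd Gaussian noise SD added to cluster mean
#'   expression profiles (mean profiles span roughly 0.5-3 units).
#' @param dag_depth Internal nodes between the DAG root and each cluster's
#'   disease leaves.
#' @param dag_branching Sibling branch nodes at the bottom of each
#'   cluster's internal chain, across which the cluster's diseases are
#'   spread.
#' @param seed Master seed; every random draw derives from it through
#'   fixed substreams, so adding a generator never perturbs earlier draws.
#' @return A list of class `fixture_params`.
#' @export
fixture_params <- function(n_lncRNAs = 60, n_clusters = 3, n_miRNAs = 30,
                           n_diseases = 18, n_mRNAs = 6, n_tissues_A = 24,
                           n_tissues_B = 12,
                           within_cluster_partner_overlap = 0.9,
                           cross_cluster_leak = 0.05,
                           expression_noise_sd = 0.25,
                           dag_depth = 3, dag_branching = 2, seed = 7) {
  p <- list(n_lncRNAs = n_lncRNAs, n_clusters = n_clusters,
            n_miRNAs = n_miRNAs, n_diseases = n_diseases, n_mRNAs = n_mRNAs,
            n_tissues_A = n_tissues_A, n_tissues_B = n_tissues_B,
            within_cluster_partner_overlap = within_cluster_partner_overlap,
            cross_cluster_leak = cross_cluster_leak,
            expression_noise_sd = expression_noise_sd,
            dag_depth = dag_depth, dag_branching = dag_branching,
            seed = seed)
  stopifnot(n_clusters >= 2, n_lncRNAs >= n_clusters,
            n_miRNAs >= n_clusters, n_diseases >= n_clusters,
            n_mRNAs >= n_clusters, n_tissues_A >= 3, n_tissues_B >= 3,
            within_cluster_partner_overlap > 0,
            within_cluster_partner_overlap <= 1,
            cross_cluster_leak >= 0, cross_cluster_leak < 1,
            within_cluster_partner_overlap > cross_cluster_leak,
            expression_noise_sd >= 0, dag_depth >= 1, dag_branching >= 1)
  structure(p, class = "fixture_params")
}

# pool ownership: entity i of n belongs to cluster by contiguous blocks
split_pool <- function(ids, n_clusters) {
  split(ids, sort(rep_len(seq_len(n_clusters), length(ids))))
}

#' Generate a synthetic fixture bundle
#'
#' @param params A `fixture_params` object.
#' @return A list of class `fixture_bundle` with elements `dag` (edge data
#'   frame), `misim` (square matrix), `lnc_mirna`, `lnc_disease`,
#'   `lnc_mrna` (`interaction_table`s), `expr_A`, `expr_B` (expression
#'   matrices, TPM and FPKM), `truth` (named cluster id per lncRNA), and
#'   `params`.
#' @export
generate_fixture <- function(params = fixture_params()) {
  stopifnot(inherits(params, "fixture_params"))
  p <- params
  k <- p$n_clusters
  lnc_ids <- sprintf("LNC%03d", seq_len(p$n_lncRNAs))
  mir_ids <- sprintf("MIR%03d", seq_len(p$n_miRNAs))
  dis_ids <- sprintf("DIS%03d", seq_len(p$n_diseases))
  mrna_ids <- sprintf("GEN%03d", seq_len(p$n_mRNAs))
  tis_a <- sprintf("tissueA%02d", seq_len(p$n_tissues_A))
  tis_b <- sprintf("tissueB%02d", seq_len(p$n_tissues_B))

  truth <- rep_len(seq_len(k), p$n_lncRNAs)  # round-robin cluster labels
  names(truth) <- lnc_ids
  mir_pool <- split_pool(mir_ids, k)
  dis_pool <- split_pool(dis_ids, k)
  mrna_pool <- split_pool(mrna_ids, k)

  # disease DAG: shared root, per-cluster internal chain of dag_depth
  # nodes ending in dag_branching sibling branch nodes that carry the
  # cluster's diseases as sibling leaves
  edges <- list()
  for (c in seq_len(k)) {
    chain <- sprintf("C%d_N%d", c, seq_len(p$dag_depth))
    edges[[length(edges) + 1]] <- data.frame(parent = "ROOT",
                                             child = chain[1])
    if (p$dag_depth > 1)
      edges[[length(edges) + 1]] <- data.frame(
        parent = chain[-p$dag_depth], child = chain[-1])
    branches <- sprintf("C%d_B%d", c, seq_len(p$dag_branching))
    edges[[length(edges) + 1]] <- data.frame(
      parent = chain[p$dag_depth], child = branches)
    leaves <- dis_pool[[c]]
    edges[[length(edges) + 1]] <- data.frame(
      parent = rep_len(branches, length(leaves)), child = leaves)
  }
  dag_edges <- do.call(rbind, edges)
  rownames(dag_edges) <- NULL

  # miRNA functional similarity: high within a cluster's pool, low across
  misim <- with_substream(p$seed, 1L, {
    m <- matrix(0, p$n_miRNAs, p$n_miRNAs,
                dimnames = list(mir_ids, mir_ids))
    pool_of <- rep(seq_len(k), lengths(mir_pool))
    for (i in seq_len(p$n_miRNAs - 1)) {
      for (j in seq(i + 1, p$n_miRNAs)) {
        v <- if (pool_of[i] == pool_of[j]) stats::runif(1, 0.6, 1.0)
             else stats::runif(1, 0.0, 0.3)
        m[i, j] <- m[j, i] <- v
      }
    }
    diag(m) <- 1
    m
  })

  draw_partners <- function(stream, pools, anchor = FALSE) {
    with_substream(p$seed, stream, {
      out <- lapply(seq_len(p$n_lncRNAs), function(i) {
        cl <- truth[i]
        chosen <- unlist(lapply(seq_len(k), function(c) {
          pool <- pools[[c]]
          prob <- if (c == cl) p$within_cluster_partner_overlap
                  else p$cross_cluster_leak
          pool[stats::runif(length(pool)) < prob]
        }), use.names = FALSE)
        if (anchor) chosen <- union(pools[[cl]][1], chosen)
        if (length(chosen) == 0) chosen <- pools[[cl]][1]
        chosen
      })
      names(out) <- lnc_ids
      out
    })
  }
  # the anchor mRNA guarantees every same-cluster pair shares >= 1 target
  mir_partners <- draw_partners(2L, mir_pool)
  dis_partners <- draw_partners(3L, dis_pool)
  mrna_partners <- draw_partners(4L, mrna_pool, anchor = TRUE)

  as_table <- function(partners, kind) {
    interaction_table(rep(names(partners), lengths(partners)),
                      unlist(partners, use.names = FALSE), kind)
  }

  expr_atlas <- function(stream_means, stream_noise, tissues, unit) {
    means <- with_substream(p$seed, stream_means, {
      m <- matrix(stats::runif(k * length(tissues), 0.5, 3), nrow = k)
      m
    })
    m <- with_substream(p$seed, stream_noise, {
      noise <- matrix(stats::rnorm(p$n_lncRNAs * length(tissues),
                                   sd = p$expression_noise_sd),
                      nrow = p$n_lncRNAs)
      pmax(means[truth, , drop = FALSE] + noise, 0)
    })
    dimnames(m) <- list(lnc_ids, tissues)
    attr(m, "unit") <- unit
    m
  }

  structure(list(dag = dag_edges,
                 misim = misim,
                 lnc_mirna = as_table(mir_partners, "lncRNA-miRNA"),
                 lnc_disease = as_table(dis_partners, "lncRNA-disease"),
                 lnc_mrna = as_table(mrna_partners, "lncRNA-mRNA"),
                 expr_A = expr_atlas(5L, 6L, tis_a, "TPM"),
                 expr_B = expr_atlas(7L, 8L, tis_b, "FPKM"),
                 truth = truth,
                 params = p),
            class = "fixture_bundle")
}

#' Write a fixture bundle to a directory
#'
#' Emits every file in the exact TSV dialects the readers consume, plus a
#' `manifest.json` recording the generation parameters and seed.
#'
#' @param bundle A `fixture_bundle`.
#' @param directory Output directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_fixture <- function(bundle, directory) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  paths <- c(dag = "dag.tsv", misim = "misim.tsv",
             lnc_mirna = "lnc_mirna.tsv", lnc_disease = "lnc_disease.tsv",
             lnc_mrna = "lnc_mrna.tsv", expr_A = "expr_atlas_a.tsv",
             expr_B = "expr_atlas_b.tsv", truth = "truth.tsv",
             manifest = "manifest.json")
  paths <- vapply(paths, function(f) file.path(directory, f), "")

  write_lines <- function(lines, path) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n")
  }
  write_lines(sprintf("%s\t%s", bundle$dag$parent, bundle$dag$child),
              paths["dag"])
  write_square_tsv(bundle$misim, paths["misim"])
  for (nm in c("lnc_mirna", "lnc_disease", "lnc_mrna")) {
    tab <- bundle[[nm]]$pairs
    write_lines(sprintf("%s\t%s", tab$lncRNA, tab$partner), paths[nm])
  }
  write_expression_tsv(bundle$expr_A, paths["expr_A"])
  write_expression_tsv(bundle$expr_B, paths["expr_B"])
  write_lines(c("lncRNA\tcluster",
                sprintf("%s\t%d", names(bundle$truth), bundle$truth)),
              paths["truth"])
  manifest <- c(bundle$params)
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

write_square_tsv <- function(m, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  ids <- rownames(m)
  writeLines(c(paste(c("id", ids), collapse = "\t"),
               vapply(seq_along(ids), function(i) {
                 paste(c(ids[i], format_score(m[i, ])), collapse = "\t")
               }, "")),
             con, sep = "\n")
}

write_expression_tsv <- function(m, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  body <- matrix(format_score(m), nrow = nrow(m))
  body[is.na(m)] <- ""
  writeLines(c(paste(c("lncRNA", colnames(m)), collapse = "\t"),
               vapply(seq_len(nrow(m)), function(i) {
                 paste(c(rownames(m)[i], body[i, ]), collapse = "\t")
               }, "")),
             con, sep = "\n")
}
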