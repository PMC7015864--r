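#' Read a two-column interaction table
#'
#' Loads a tab-separated edge list linking lncRNAs to partner entities
#' (miRNAs, diseases or target mRNAs). The first column is the lncRNA id,
#' the second the partner id; extra columns are ignored. Duplicate pairs are
#' dropped (and counted in a log message), ids are whitespace-stripped.
#'
#' @param path Path to a TSV file.
#' @param kind One of `"lncRNA-miRNA"`, `"lncRNA-disease"`, `"lncRNA-mRNA"`.
#' @param header Logical; does the file start with a header row?
#' @return An object of class `interaction_table`: a list with elements
#'   `kind` and `pairs` (a data frame with columns `lncRNA`, `partner`).
#' @export
read_interaction_table <- function(path,
                                   kind = c("lncRNA-miRNA", "lncRNA-disease",
                                            "lncRNA-mRNA"),
                                   header = FALSE) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (header && length(lines) > 0) lines <- lines[-1]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty interaction table: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2)) {
    bad <- which(nf < 2)[1] + if (header) 1L else 0L
    stop(sprintf("line %d: expected 2 columns", bad))
  }
  lnc <- trimws(vapply(fields, `[[`, "", 1L))
  partner <- trimws(vapply(fields, `[[`, "", 2L))
  if (any(!nzchar(lnc)) || any(!nzchar(partner))) {
    bad <- which(!nzchar(lnc) | !nzchar(partner))[1] + if (header) 1L else 0L
    stop(sprintf("line %d: empty id", bad))
  }
  keep <- !duplicated(paste(lnc, partner, sep = "\r"))
  n_dup <- sum(!keep)
  hl_log("read %d rows from %s (%d duplicate pairs dropped)",
         length(lnc), basename(path), n_dup)
  interaction_table(lnc[keep], partner[keep], kind)
}

#' Construct an interaction table from vectors
#'
#' @param lncRNA,partner Character vectors of equal length.
#' @param kind Interaction kind label.
#' @return An `interaction_table`.
#' @export
interaction_table <- function(lncRNA, partner, kind) {
  stopifnot(length(lncRNA) == length(partner))
  pairs <- data.frame(lncRNA = as.character(lncRNA),
                      partner = as.character(partner),
                      stringsAsFactors = FALSE)
  pairs <- pairs[!duplicated(paste(pairs$lncRNA, pairs$partner, sep = "\r")), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(kind = kind, pairs = pairs), class = "interaction_table")
}

#' @export
print.interaction_table <- function(x, ...) {
  cat(sprintf("interaction_table <%s>: %d pairs, %d lncRNAs, %d partners\n",
              x$kind, nrow(x$pairs), length(unique(x$pairs$lncRNA)),
              length(unique(x$pairs$partner))))
  invisible(x)
}

# partner ids per lncRNA, as a named list
partner_sets <- function(tab) {
  split(tab$pairs$partner, tab$pairs$lncRNA)
}

#' Read a square similarity matrix
#'
#' Reads a TSV with a header row and a leading id column (MISIM-style miRNA
#' functional similarity). The diagonal is forced to 1; off-diagonal
#' asymmetries in the source are reconciled by the `symmetrize` rule;
#' values outside \[0, 1\] are clamped with a warning.
#'
#' @param path Path to a TSV file.
#' @param symmetrize `"average"` (default), `"max"`, or `"error"` — how to
#'   reconcile `m[i,j] != m[j,i]`.
#' @return A numeric matrix with identical row/column names, unit diagonal,
#'   symmetric, entries in \[0, 1\].
#' @export
read_square_matrix <- function(path, symmetrize = c("average", "max", "error")) {
  symmetrize <- match.arg(symmetrize)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  ids <- rownames(raw)
  if (anyDuplicated(ids) || anyDuplicated(colnames(raw)))
    stop("duplicated ids in square matrix")
  if (nrow(raw) != ncol(raw)) stop("matrix not square")
  if (!identical(ids, colnames(raw)))
    stop("row and column ids differ in square matrix")
  m <- suppressWarnings(matrix(as.numeric(as.matrix(raw)), nrow = nrow(raw),
                               dimnames = list(ids, ids)))
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at row %s, column %s",
                 ids[bad[1]], ids[bad[2]]))
  }
  n_clamp <- sum(m < 0 | m > 1)
  if (n_clamp > 0) {
    hl_warn("%d similarity values outside [0,1] clamped", n_clamp)
    m <- pmin(pmax(m, 0), 1)
  }
  tm <- t(m)
  if (any(abs(m - tm) > 1e-9)) {
    m <- switch(symmetrize,
                average = (m + tm) / 2,
                max = pmax(m, tm),
                error = stop("matrix not symmetric"))
  }
  diag(m) <- 1
  m
}

#' Read an expression matrix
#'
#' TSV with a header row; first column is the lncRNA id, remaining columns
#' one per tissue/organ. Blank cells become `NA` (missing, distinct from
#' zero); negative values are an error.
#'
#' @param path Path to a TSV file.
#' @param unit `"TPM"` or `"FPKM"`; recorded as the matrix's `unit`
#'   attribute. Matrices with different units are never merged.
#' @return A numeric matrix (rows = lncRNAs, columns = tissues) with
#'   attribute `unit`.
#' @export
read_expression_matrix <- function(path, unit = c("TPM", "FPKM")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  ids <- trimws(raw[[1]])
  if (anyDuplicated(ids)) stop("duplicate lncRNA ids in expression matrix")
  body <- as.matrix(raw[, -1, drop = FALSE])
  body[trimws(body) == ""] <- NA
  m <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body),
                               dimnames = list(ids, colnames(raw)[-1])))
  not_numeric <- is.na(m) & !is.na(body) & trimws(body) != "NA"
  if (any(not_numeric)) {
    bad <- which(not_numeric, arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric expression value at row %s, column %s",
                 ids[bad[1]], colnames(m)[bad[2]]))
  }
  neg <- which(!is.na(m) & m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop(sprintf("negative expression value at row %s, column %s",
                 ids[neg[1, 1]], colnames(m)[neg[1, 2]]))
  }
  attr(m, "unit") <- unit
  m
}

#' Read a disease-hierarchy DAG edge list
#'
#' TSV with two columns, `parent` then `child` (MeSH-style hierarchy).
#' Duplicate edges are dropped; self-loops are an error.
#'
#' @param path Path to a TSV file.
#' @return A data frame with columns `parent`, `child`.
#' @export
read_dag_edges <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty DAG edge list: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2)) {
    stop(sprintf("line %d: expected 2 columns", which(lengths(fields) < 2)[1]))
  }
  parent <- trimws(vapply(fields, `[[`, "", 1L))
  child <- trimws(vapply(fields, `[[`, "", 2L))
  if (any(parent == child)) {
    stop("self-loop in DAG edge list: ", parent[parent == child][1])
  }
  keep <- !duplicated(paste(parent, child, sep = "\r"))
  data.frame(parent = parent[keep], child = child[keep],
             stringsAsFactors = FALSE)
}

#' Construct a similarity network
#'
#' A similarity network is one evidence layer's scored lncRNA pairs plus the
#' set of lncRNAs the layer can score at all (its coverage). Pairs are
#' stored unordered, smaller id first; self-pairs are never stored.
#'
#' @param name Evidence-layer label (e.g. `"mirna"`, `"disease"`, `"GTEx"`).
#' @param coverage Character vector of lncRNA ids the layer covers.
#' @param lncA,lncB,score Parallel vectors defining scored pairs.
#' @return An object of class `similarity_network` with elements `name`,
#'   `coverage`, and `scores` (data frame `lncA`, `lncB`, `score`).
#' @export
similarity_network <- function(name, coverage, lncA = character(),
                               lncB = character(), score = numeric()) {
  stopifnot(length(lncA) == length(lncB), length(lncA) == length(score))
  if (length(lncA) > 0) {
    if (any(lncA == lncB)) stop("self-pairs are not stored")
    cp <- canonical_pairs(lncA, lncB)
    keys <- pair_key(cp$lncA, cp$lncB)
    if (anyDuplicated(keys)) stop("duplicate pair in similarity network")
    if (!all(c(cp$lncA, cp$lncB) %in% coverage))
      stop("scored pair outside coverage")
    scores <- data.frame(cp, score = as.numeric(score))
    scores <- scores[order(scores$lncA, scores$lncB, method = "radix"), ,
                     drop = FALSE]
    rownames(scores) <- NULL
  } else {
    scores <- data.frame(lncA = character(), lncB = character(),
                         score = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(name = name, coverage = sort(unique(coverage),
                                              method = "radix"),
                 scores = scores),
            class = "similarity_network")
}

#' @export
print.similarity_network <- function(x, ...) {
  cat(sprintf("similarity_network '%s': %d lncRNAs covered, %d scored pairs\n",
              x$name, length(x$coverage), nrow(x$scores)))
  invisible(x)
}

#' Write a similarity network to TSV
#'
#' @param net A `similarity_network`.
#' @param path Output file path.
#' @param shape `"long"` (three columns `lncA`, `lncB`, `score`, smaller id
#'   first) or `"square"` (full symmetric matrix over the coverage set, unit
#'   diagonal, blank cells for unscored pairs).
#' @return Invisibly, `path`.
#' @export
write_similarity_network <- function(net, path, shape = c("long", "square")) {
  shape <- match.arg(shape)
  stopifnot(inherits(net, "similarity_network"))
  if (nrow(net$scores) == 0) stop("refusing to write an empty network")
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (shape == "long") {
    writeLines(c("lncA\tlncB\tscore",
                 sprintf("%s\t%s\t%s", net$scores$lncA, net$scores$lncB,
                         format_score(net$scores$score))),
               con, sep = "\n")
  } else {
    ids <- net$coverage
    m <- matrix("", length(ids), length(ids), dimnames = list(ids, ids))
    diag(m) <- "1"
    sc <- format_score(net$scores$score)
    idx_a <- match(net$scores$lncA, ids)
    idx_b <- match(net$scores$lncB, ids)
    m[cbind(idx_a, idx_b)] <- sc
    m[cbind(idx_b, idx_a)] <- sc
    writeLines(c(paste(c("id", ids), collapse = "\t"),
                 vapply(seq_along(ids), function(i) {
                   paste(c(ids[i], m[i, ]), collapse = "\t")
                 }, "")),
               con, sep = "\n")
  }
  invisible(path)
}

#' Read a long-form similarity network TSV
#'
#' Inverse of [write_similarity_network()] with `shape = "long"`. The
#' coverage set is taken as the union of ids appearing in scored pairs.
#'
#' @param path Path to a TSV written in long shape (header `lncA lncB score`).
#' @param name Layer label to attach; defaults to the file's base name.
#' @return A `similarity_network`.
#' @export
read_similarity_network <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "character", "numeric"),
                           quote = "", comment.char = "")
  if (ncol(tab) < 3) stop("expected 3 columns: lncA, lncB, score")
  similarity_network(name %||% sub("\\.[^.]*$", "", basename(path)),
                     coverage = unique(c(tab[[1]], tab[[2]])),
                     lncA = tab[[1]], lncB = tab[[2]], score = tab[[3]])
}
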