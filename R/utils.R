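# Internal helpers shared across modules: pair canonicalization, seeded
# substreams, and stderr logging.

# All lncRNA pairs are unordered; the canonical form stores the
# lexicographically smaller id first (C collation, locale-independent).
canonical_pairs <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  swap <- cmp_lt(b, a)
  first <- ifelse(swap, b, a)
  second <- ifelse(swap, a, b)
  data.frame(lncA = first, lncB = second, stringsAsFactors = FALSE)
}

# Locale-independent "<" on character vectors.
cmp_lt <- function(x, y) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  x < y
}

pair_key <- function(lncA, lncB) paste(lncA, lncB, sep = "\r")

# Derives an independent 32-bit substream seed from a master seed and a
# stream index, so that adding a consumer never perturbs earlier streams.
substream_seed <- function(seed, stream) {
  (as.double(seed) %% 2147483647) * 69621 %% 2147483647 + stream * 10007
}

with_substream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(substream_seed(seed, stream) %% 2147483647))
  force(expr)
}

hl_log <- function(fmt, ..., level = "INFO") {
  message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

hl_warn <- function(fmt, ...) hl_log(fmt, ..., level = "WARN")

# Numbers are always written with "." decimal and full precision so output
# files are byte-stable across locales and runs.
format_score <- function(x) {
  sprintf("%.15g", x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
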