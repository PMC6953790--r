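## Internal helpers: chromosome-label normalization, classed conditions,
## deterministic per-sample RNG streams, small interval arithmetic.

#' Normalize chromosome labels
#'
#' Strips a leading `"chr"` prefix so that `"chr17"`, `"Chr17"` and `"17"`
#' all map to the canonical un-prefixed form `"17"` used internally.
#'
#' @param x character vector of chromosome labels.
#' @return character vector of canonical labels.
#' @export
norm_chrom <- function(x) {
  sub("^[Cc][Hh][Rr]", "", as.character(x))
}

stop_segstack <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "segstack_error")))
}

parse_error <- function(msg) stop_segstack(msg, "segstack_parse_error")
validation_error <- function(msg) stop_segstack(msg, "segstack_validation_error")
io_error <- function(msg) stop_segstack(msg, "segstack_io_error")

## 1bp-or-more intersection of half-open intervals (vectorized)
iv_overlaps <- function(s1, e1, s2, e2) {
  pmax(s1, s2) < pmin(e1, e2)
}

## Stable 31-adic string hash on [0, 2^31 - 2], in double arithmetic.
str_hash <- function(x) {
  m <- 2147483647
  vapply(x, function(s) {
    h <- 0
    for (c in utf8ToInt(s)) h <- (h * 31 + c) %% m
    h
  }, numeric(1))
}

## One pseudo-random stream per (seed, label): evaluates `expr` under a
## sub-seed so adding a sample never perturbs another sample's draws.
with_stream <- function(seed, label, expr) {
  sub_seed <- as.integer((as.double(seed) * 48271 + str_hash(label)) %% 2147483647)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(sub_seed)
  expr
}

## Read a possibly-gzipped delimited text file into a data.table.
## gzfile() autodetects compression, so plain files work unchanged.
read_table_text <- function(path, ...) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0) parse_error(sprintf("empty file: %s", path))
  data.table::fread(text = paste(lines, collapse = "\n"), ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
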