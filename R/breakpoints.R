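## Breakpoint feature classification and the iso-chromosomal permutation
## null: each CNA edge is tested against telomere windows, centromere
## windows, gene spans and fragile/stable-site tracks; the null relocates
## every call to a uniform random position on its own chromosome,
## preserving its length.

EDGE_CATEGORIES <- c("telomeric", "centromeric", "intragenic", "fragile",
                     "stable")

## membership of points in an interval track (half-open [start, end))
points_in_track <- function(chrom, pos, track) {
  if (nrow(track) == 0L) return(rep(FALSE, length(pos)))
  hit <- rep(FALSE, length(pos))
  for (ch in unique(chrom)) {
    tr <- track[track$chrom == ch]
    if (nrow(tr) == 0L) next
    sel <- which(chrom == ch)
    for (i in seq_len(nrow(tr)))
      hit[sel] <- hit[sel] | (pos[sel] >= tr$start[i] & pos[sel] < tr$end[i])
  }
  hit
}

## all (point, gene) containments; returns per-point list of gene ids
genes_at_points <- function(chrom, pos, genes) {
  hits <- rep(list(character(0)), length(pos))
  if (nrow(genes) == 0L) return(hits)
  pts <- data.table::data.table(chrom = chrom, start = pos, end = pos,
                                idx = seq_along(pos))
  ## half-open gene [gs, ge): point hits iff gs <= pos <= ge - 1
  g <- data.table::data.table(chrom = genes$chrom, start = genes$start,
                              end = genes$end - 1, gene_id = genes$gene_id)
  data.table::setkey(g, chrom, start, end)
  ov <- data.table::foverlaps(pts, g, type = "within", nomatch = NULL)
  if (nrow(ov)) {
    by_idx <- split(ov$gene_id, ov$idx)
    hits[as.integer(names(by_idx))] <- by_idx
  }
  hits
}

#' Classify CNA edges against genomic feature tracks
#'
#' Each call contributes two edges (its start and end breakpoints); each
#' edge is classified independently with non-exclusive flags:
#' `telomeric` (within the telomere window of a chromosome end, default
#' 2 Mb), `centromeric` (inside the centromere interval expanded by the
#' same window on both flanks), `intragenic` (inside any gene span, with
#' all overlapped genes listed), `fragile` and `stable` (inside the
#' respective site tracks).
#'
#' @param calls a `cna_calls` table (or any data.frame with `sample`,
#'   `chrom`, `start`, `end`).
#' @param annotation a [genome_annotation()] covering all call
#'   chromosomes.
#' @return data.table of class `edge_classification`: one row per edge
#'   with `call_id`, `sample`, `chrom`, `pos`, `edge` (`"start"`/`"end"`),
#'   the five logical flags, and `genes_hit` (list column).
#' @export
classify_edges <- function(calls, annotation) {
  calls <- data.table::as.data.table(calls)
  unknown <- setdiff(unique(calls$chrom),
                     names(annotation$build$chrom_lengths))
  if (length(unknown))
    validation_error(sprintf("call(s) on chromosome(s) absent from annotation: %s",
                             paste(unknown, collapse = ", ")))
  n <- nrow(calls)
  edges <- data.table::data.table(
    call_id = rep(seq_len(n), 2L),
    sample = rep(if ("sample" %in% names(calls)) calls$sample
                 else NA_character_, 2L),
    chrom = rep(calls$chrom, 2L),
    pos = c(calls$start, calls$end),
    edge = rep(c("start", "end"), each = n))
  W <- annotation$telomere_window_bp
  L <- annotation$build$chrom_lengths[edges$chrom]
  data.table::set(edges, j = "telomeric",
                  value = edges$pos < W | (L - edges$pos) < W)
  cen <- data.table::copy(annotation$centromeres)
  if (nrow(cen)) {
    cen[, `:=`(start = pmax(start - W, 0), end = end + W)]
  }
  data.table::set(edges, j = "centromeric",
                  value = points_in_track(edges$chrom, edges$pos, cen))
  gh <- genes_at_points(edges$chrom, edges$pos, annotation$genes)
  data.table::set(edges, j = "intragenic",
                  value = lengths(gh) > 0L)
  data.table::set(edges, j = "fragile",
                  value = points_in_track(edges$chrom, edges$pos,
                                          annotation$fragile_sites))
  data.table::set(edges, j = "stable",
                  value = points_in_track(edges$chrom, edges$pos,
                                          annotation$stable_sites))
  data.table::set(edges, j = "genes_hit", value = gh)
  data.table::setattr(edges, "class", c("edge_classification", class(edges)))
  edges
}

#' Sizes and expression of genes overlapped by CNA edges
#'
#' For every intragenic edge, emits the overlapped gene's span length (bp)
#' and, when an expression table is attached to the annotation, its
#' expression value.  Edges hitting several genes emit all of them; genes
#' with no expression entry contribute a length but no expression value.
#'
#' @param classifications an [classify_edges()] result.
#' @param annotation the same [genome_annotation()].
#' @return list with `gene_ids`, `sizes` (bp) and `expression`.
#' @export
genes_at_edges <- function(classifications, annotation) {
  ids <- unlist(classifications$genes_hit, use.names = FALSE)
  if (is.null(ids)) ids <- character()
  sizes <- annotation$genes$length[match(ids, annotation$genes$gene_id)]
  expr <- if (!is.null(annotation$expression)) {
    e <- annotation$expression[ids]
    unname(e[!is.na(e)])
  } else numeric()
  list(gene_ids = ids, sizes = sizes, expression = expr)
}

edge_category_counts <- function(classifications) {
  vapply(EDGE_CATEGORIES, function(k) sum(classifications[[k]]), integer(1))
}

#' Iso-chromosomal permutation null for CNA edges
#'
#' Relocates every call to a uniform random start in
#' `[0, chrom_length - call_length]` on its own chromosome — preserving
#' chromosome and exact length — reclassifies the edges, and records per
#' permutation the per-category edge counts plus the sizes and expression
#' of genes overlapped by edges.  Fully reproducible for a fixed seed.
#'
#' @param calls a `cna_calls` table.
#' @param annotation a [genome_annotation()].
#' @param n number of permutations (default 1000).
#' @param seed RNG seed.
#' @return object of class `permutation_null`: `n_permutations`, `seed`,
#'   `counts` (n x 5 matrix over the edge categories), `gene_sizes`,
#'   `expression` (per-permutation lists), and `permuted_calls` (the
#'   data.table of all permuted placements, with a `perm` column).
#' @export
permute_isochromosomal <- function(calls, annotation, n = 1000, seed = 1L) {
  calls <- data.table::as.data.table(calls)
  k <- nrow(calls)
  if (k == 0L) validation_error("no calls to permute")
  L <- annotation$build$chrom_lengths[calls$chrom]
  if (anyNA(L))
    validation_error("call chromosome(s) absent from annotation build")
  len <- calls$end - calls$start
  too_long <- which(len > L)
  if (length(too_long))
    validation_error(sprintf(
      "call(s) longer than their chromosome: %s",
      paste(sprintf("%s:%d-%d", calls$chrom[too_long],
                    calls$start[too_long], calls$end[too_long]),
            collapse = ", ")))
  set.seed(as.integer(seed))
  starts <- floor(stats::runif(n * k, min = 0,
                               max = rep(unname(L - len), n) + 1))
  starts <- pmin(starts, rep(unname(L - len), n))  # guard the open endpoint
  perm_calls <- data.table::data.table(
    perm = rep(seq_len(n), each = k),
    sample = rep(if ("sample" %in% names(calls)) calls$sample
                 else NA_character_, n),
    chrom = rep(calls$chrom, n),
    start = starts,
    end = starts + rep(len, n))
  cls <- classify_edges(perm_calls, annotation)
  pid <- rep(rep(seq_len(n), each = k), 2L)  # perm id per edge row
  counts <- matrix(0L, nrow = n, ncol = length(EDGE_CATEGORIES),
                   dimnames = list(NULL, EDGE_CATEGORIES))
  for (cat in EDGE_CATEGORIES) {
    tab <- tabulate(pid[cls[[cat]]], nbins = n)
    counts[, cat] <- tab
  }
  by_perm <- split(seq_len(nrow(cls)), pid)
  gene_sizes <- vector("list", n)
  expression <- vector("list", n)
  for (p in seq_len(n)) {
    ge <- genes_at_edges(cls[by_perm[[p]]], annotation)
    gene_sizes[[p]] <- ge$sizes
    expression[[p]] <- ge$expression
  }
  structure(list(n_permutations = n, seed = seed, counts = counts,
                 gene_sizes = gene_sizes, expression = expression,
                 permuted_calls = perm_calls),
            class = "permutation_null")
}

#' Empirical enrichment of edge categories against the permutation null
#'
#' For each category, the add-one empirical p-value for enrichment is
#' `(1 + #\{permutations with count >= observed\}) / (n + 1)` (never 0
#' from finite permutations); the two-sided option doubles the smaller
#' tail and caps at 1.  Per-Mb rates (count divided by the genomic extent
#' of the category's track) are reported alongside raw counts since both
#' normalizations are in common use.
#'
#' @param observed an [classify_edges()] result for the real calls.
#' @param null a [permute_isochromosomal()] result built from the same
#'   calls.
#' @param annotation optional [genome_annotation()]; when given, per-Mb
#'   rates are added.
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`.
#' @return data.table: `category`, `observed`, `null_mean`, `p_value`
#'   (and `track_mb`, `observed_per_mb` when annotation is given).
#' @export
enrichment <- function(observed, null, annotation = NULL,
                       alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  obs <- edge_category_counts(observed)
  n <- null$n_permutations
  p <- vapply(EDGE_CATEGORIES, function(cat) {
    hi <- (1 + sum(null$counts[, cat] >= obs[cat])) / (n + 1)
    if (alternative == "greater") return(hi)
    lo <- (1 + sum(null$counts[, cat] <= obs[cat])) / (n + 1)
    min(1, 2 * min(hi, lo))
  }, numeric(1))
  out <- data.table::data.table(
    category = EDGE_CATEGORIES, observed = as.integer(obs),
    null_mean = colMeans(null$counts)[EDGE_CATEGORIES], p_value = p)
  if (!is.null(annotation)) {
    track_bp <- c(
      telomeric = {
        tw <- telomere_windows(annotation); sum(tw$end - tw$start)
      },
      centromeric = if (nrow(annotation$centromeres)) {
        W <- annotation$telomere_window_bp
        sum(pmin(annotation$centromeres$end + W,
                 annotation$build$chrom_lengths[annotation$centromeres$chrom]) -
              pmax(annotation$centromeres$start - W, 0))
      } else 0,
      intragenic = sum(annotation$genes$length),
      fragile = sum(annotation$fragile_sites$end -
                      annotation$fragile_sites$start),
      stable = sum(annotation$stable_sites$end -
                     annotation$stable_sites$start))
    data.table::set(out, j = "track_mb",
                    value = unname(track_bp[EDGE_CATEGORIES]) / 1e6)
    data.table::set(out, j = "observed_per_mb",
                    value = ifelse(out$track_mb > 0,
                                   out$observed / out$track_mb, NA_real_))
  }
  out
}
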