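## Co-alteration query engine: classify each tumor's relationship to one or
## two query regions (exclusive / coincident deletion or amplification),
## summarize a cohort, and pull segments terminating inside a region
## (e.g. telo-centric events).

as_region <- function(x, annotation = NULL) {
  if (is.character(x) && length(x) == 1L) {
    if (is.null(annotation))
      validation_error("gene-name regions need an annotation to resolve them")
    return(gene_region(annotation, x))
  }
  x <- as.list(x)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x)))
    validation_error("a region needs chrom, start and end")
  r <- list(chrom = norm_chrom(x$chrom), start = as.double(x$start),
            end = as.double(x$end), id = x$id %||% NA_character_)
  if (!is.finite(r$start) || !is.finite(r$end) || r$start >= r$end ||
      r$start < 0)
    validation_error("region must satisfy 0 <= start < end")
  r
}

#' Build a co-alteration region query
#'
#' Defines the one or two genomic regions and the direction (copy loss or
#' gain) against which every sample of a cohort is classified.  A segment
#' "qualifies" for a region when it overlaps it by at least 1 bp and its
#' log2 ratio passes the direction's threshold (`log2 <= loss_threshold`
#' for losses, `log2 >= gain_threshold` for gains).
#'
#' @param region_a first region: a list with `chrom`, `start`, `end` (and
#'   optional `id`), or a gene name resolved via `annotation`.
#' @param region_b optional second region (same forms).  May be on a
#'   different chromosome; such a pair can never be coincident via a
#'   single segment but can still be coincident per tumor.
#' @param direction `"loss"` or `"gain"`.
#' @param loss_threshold,gain_threshold log2 cutoffs; defaults -0.2 / +0.2,
#'   the conventional cutoff for calling a segment deviant from ploidy.
#' @param annotation optional [genome_annotation()] for gene-name lookup.
#' @return object of class `region_query`.
#' @export
region_query <- function(region_a, region_b = NULL,
                         direction = c("loss", "gain"),
                         loss_threshold = -0.2, gain_threshold = 0.2,
                         annotation = NULL) {
  direction <- match.arg(direction)
  if (!(loss_threshold < 0 && gain_threshold > 0))
    validation_error("need loss_threshold < 0 < gain_threshold")
  structure(list(
    region_a = as_region(region_a, annotation),
    region_b = if (!is.null(region_b)) as_region(region_b, annotation),
    direction = direction, loss_threshold = loss_threshold,
    gain_threshold = gain_threshold), class = "region_query")
}

qualifying_segments <- function(segs, region, direction, loss_threshold,
                                gain_threshold) {
  hit <- segs$chrom == region$chrom &
    iv_overlaps(segs$start, segs$end, region$start, region$end)
  pass <- if (direction == "loss") segs$log2 <= loss_threshold
          else segs$log2 >= gain_threshold
  segs[hit & pass]
}

#' Classify one sample against a region query
#'
#' @param profile a [sample_profile()] (or a single-sample cohort).
#' @param query a [region_query()].
#' @param single_segment if `TRUE`, coincidence additionally requires one
#'   segment that spans both regions; by default coincidence is a
#'   per-tumor property (two separate qualifying segments also count).
#' @return list of class `sample_classification`: `sample_id`, `category`
#'   (one of `exclusive_a`, `exclusive_b`, `coincident`, `none`) and
#'   `supporting_segments` (a data.table; empty iff category is `none`).
#' @export
classify_sample <- function(profile, query, single_segment = FALSE) {
  segs <- as_profile_segments(profile)
  sid <- if (is.list(profile) && !is.null(profile$sample_id))
    profile$sample_id else unique(segs$sample)
  if (length(sid) != 1L)
    validation_error("classify_sample needs exactly one sample")
  build <- if (is.list(profile)) profile$build else NULL
  if (!is.null(build)) {
    for (r in list(query$region_a, query$region_b))
      if (!is.null(r)) chrom_length(build, r$chrom)
  }
  qa <- qualifying_segments(segs, query$region_a, query$direction,
                            query$loss_threshold, query$gain_threshold)
  qb <- if (is.null(query$region_b)) qa[0L]
        else qualifying_segments(segs, query$region_b, query$direction,
                                 query$loss_threshold, query$gain_threshold)
  a_hit <- nrow(qa) > 0L
  b_hit <- nrow(qb) > 0L
  spanning <- if (a_hit && b_hit && single_segment) {
    both <- qa[qa$chrom == query$region_b$chrom &
                 iv_overlaps(qa$start, qa$end, query$region_b$start,
                             query$region_b$end)]
    nrow(both) > 0L
  } else TRUE
  category <- if (a_hit && b_hit && spanning) "coincident"
    else if (a_hit) "exclusive_a"
    else if (b_hit) "exclusive_b"
    else "none"
  supp <- unique(data.table::rbindlist(list(
    if (category %in% c("exclusive_a", "coincident")) qa,
    if (category %in% c("exclusive_b", "coincident")) qb)))
  structure(list(sample_id = sid, category = category,
                 supporting_segments = supp),
            class = "sample_classification")
}

#' Summarize co-alteration categories over a cohort
#'
#' Classifies every sample of the cohort against the query and tallies the
#' four categories.  Counts always partition the cohort:
#' `exclusive_a + exclusive_b + coincident + none == n_samples`.
#'
#' @param x a `segstack_cohort` (non-empty).
#' @param query a [region_query()].
#' @param single_segment see [classify_sample()].
#' @return object of class `cairn_summary` with `counts` (named integer
#'   vector over the four categories), `table` (per-sample data.table:
#'   `sample`, `category`, `n_supporting`, `min_log2`), plus the query and
#'   cohort for downstream rendering.
#' @export
cohort_summary <- function(x, query, single_segment = FALSE) {
  ids <- sample_ids(x)
  rows <- lapply(ids, function(id) {
    cl <- classify_sample(sample_profile(x, id), query,
                          single_segment = single_segment)
    data.table::data.table(
      sample = id, category = cl$category,
      n_supporting = nrow(cl$supporting_segments),
      min_log2 = if (nrow(cl$supporting_segments))
        min(cl$supporting_segments$log2) else NA_real_)
  })
  tab <- data.table::rbindlist(c(list(data.table::data.table(
    sample = character(), category = character(),
    n_supporting = integer(), min_log2 = double())), rows))
  counts <- vapply(c("exclusive_a", "exclusive_b", "coincident", "none"),
                   function(k) sum(tab$category == k), integer(1))
  structure(list(counts = counts, table = tab, query = query, cohort = x),
            class = "cairn_summary")
}

#' @export
print.cairn_summary <- function(x, ...) {
  cat(sprintf("<cairn_summary> %s query over %d samples\n",
              x$query$direction, sum(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Segments terminating inside a region
#'
#' Returns direction-qualifying segments with at least one endpoint inside
#' `region` — the query behind telo-centric CNA extraction, where a
#' breakage-fusion-bridge-style event runs from a breakpoint to the
#' chromosome end.  The start endpoint is inside `[s, e)` when
#' `s <= start < e`; the end endpoint when `s < end <= e`.
#'
#' @param x a `segstack_cohort`.
#' @param region list with `chrom`, `start`, `end`.
#' @param direction `"loss"` or `"gain"`.
#' @param loss_threshold,gain_threshold log2 cutoffs (defaults ±0.2).
#' @return data.table of qualifying segments with logical columns
#'   `start_in`, `end_in` flagging which endpoint(s) fell inside.
#' @export
segments_terminating_in <- function(x, region, direction = c("loss", "gain"),
                                    loss_threshold = -0.2,
                                    gain_threshold = 0.2) {
  direction <- match.arg(direction)
  r <- as_region(region)
  segs <- x$segments
  pass <- if (direction == "loss") segs$log2 <= loss_threshold
          else segs$log2 >= gain_threshold
  on_chrom <- segs$chrom == r$chrom
  start_in <- on_chrom & pass & segs$start >= r$start & segs$start < r$end
  end_in <- on_chrom & pass & segs$end > r$start & segs$end <= r$end
  keep <- start_in | end_in
  out <- segs[keep]
  data.table::set(out, j = "start_in", value = start_in[keep])
  data.table::set(out, j = "end_in", value = end_in[keep])
  out
}
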