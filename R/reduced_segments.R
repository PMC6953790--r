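## Reduced-segment machinery: project every sample onto the union of all
## samples' breakpoints so profiles become directly comparable columns,
## then call differential CNAs against a control-mean baseline and count
## discrete events per chromosome.

#' Build the reduced-segment matrix of a cohort
#'
#' Takes the union of all samples' segment breakpoints per chromosome and
#' re-tiles the covered extent into "reduced segments": maximal intervals
#' within which no sample has a breakpoint.  Every sample then has exactly
#' one value per tile — the log2 of the unique original segment containing
#' it, or `NA` where that sample has no coverage.  This is the classic
#' cross-sample reduction used to compare segmented profiles
#' breakpoint-by-breakpoint.
#'
#' @param x a `segstack_cohort` (each sample's segments non-overlapping).
#' @return object of class `reduced_matrix`: `values` (samples x tiles
#'   numeric matrix, rownames = sample ids), `segments` (data.table
#'   `chrom`, `start`, `end`, one row per tile, genome order), and
#'   `boundaries` (per-chromosome sorted breakpoint vectors).
#' @export
reduce_segments <- function(x) {
  segs <- x$segments
  if (nrow(segs) == 0L) validation_error("cohort has no segments")
  samples <- sample_ids(x)
  chroms <- sort(unique(segs$chrom))
  tiles_list <- vector("list", length(chroms))
  boundaries <- stats::setNames(vector("list", length(chroms)), chroms)
  for (ci in seq_along(chroms)) {
    cs <- segs[segs$chrom == chroms[ci]]
    b <- sort(unique(c(cs$start, cs$end)))
    boundaries[[ci]] <- b
    t_start <- b[-length(b)]
    t_end <- b[-1L]
    ## keep only tiles covered by at least one sample (sweep-line count)
    cover <- cumsum(
      vapply(t_start, function(p) sum(cs$start == p) - sum(cs$end == p),
             numeric(1)))
    keep <- cover > 0
    tiles_list[[ci]] <- data.table::data.table(
      chrom = chroms[ci], start = t_start[keep], end = t_end[keep])
  }
  tiles <- data.table::rbindlist(tiles_list)
  values <- matrix(NA_real_, nrow = length(samples), ncol = nrow(tiles),
                   dimnames = list(samples, NULL))
  for (s in samples) {
    ss <- segs[segs$sample == s]
    for (ci in seq_along(chroms)) {
      sc <- ss[ss$chrom == chroms[ci]]
      if (nrow(sc) == 0L) next
      idx <- which(tiles$chrom == chroms[ci])
      pos <- findInterval(tiles$start[idx], sc$start)
      ok <- pos >= 1L & tiles$end[idx] <= sc$end[pmax(pos, 1L)]
      values[s, idx[ok]] <- sc$log2[pos[ok]]
    }
  }
  structure(list(values = values, segments = tiles, boundaries = boundaries),
            class = "reduced_matrix")
}

#' @export
print.reduced_matrix <- function(x, ...) {
  cat(sprintf("<reduced_matrix> %d samples x %d reduced segments (%d chromosomes)\n",
              nrow(x$values), ncol(x$values), length(x$boundaries)))
  invisible(x)
}

#' Convert a reduced matrix back into a cohort
#'
#' Each sample's non-missing tiles become segments verbatim (no merging of
#' equal-valued neighbours), so [reduce_segments()] is idempotent on the
#' result.
#'
#' @param x a `reduced_matrix`.
#' @param build optional [genome_build()] for the resulting cohort.
#' @return a `segstack_cohort`.
#' @export
as_cohort <- function(x, build = NULL) {
  stopifnot(inherits(x, "reduced_matrix"))
  rows <- lapply(rownames(x$values), function(s) {
    v <- x$values[s, ]
    keep <- !is.na(v)
    data.table::data.table(sample = s, chrom = x$segments$chrom[keep],
                           start = x$segments$start[keep],
                           end = x$segments$end[keep], log2 = v[keep])
  })
  cohort(data.table::rbindlist(rows), build = build)
}

#' Control-mean baseline over reduced segments
#'
#' The per-tile unweighted mean of the control samples — the "normal"
#' reference against which differential CNAs are called.  A tile missing
#' in any control is missing in the baseline (no imputation).
#'
#' @param x a `reduced_matrix`.
#' @param control_ids character vector of control sample ids (>= 1).
#' @return numeric vector, one value per reduced segment.
#' @export
baseline_mean <- function(x, control_ids) {
  if (length(control_ids) == 0L) validation_error("empty control set")
  missing_ids <- setdiff(control_ids, rownames(x$values))
  if (length(missing_ids))
    validation_error(sprintf("control id(s) not in matrix: %s",
                             paste(missing_ids, collapse = ", ")))
  colMeans(x$values[control_ids, , drop = FALSE])
}

size_class_of <- function(len) {
  ifelse(len < 1e5, "focal", ifelse(len > 1e6, "large", "intermediate"))
}

#' Call differential CNAs against a baseline
#'
#' A reduced segment is called in a sample when its deviation from the
#' baseline is at least `threshold` log2 units in magnitude.  With
#' `merge = TRUE` (default), genomically adjacent called tiles of one
#' sample with the same direction merge into a single event (gap tolerance
#' 0 bp; missing tiles break merges), so event counts reflect discrete
#' CNAs rather than segmentation granularity.  Event size classes follow
#' the usual focal/large convention: focal `< 100 kb`, large `> 1 Mb`,
#' intermediate otherwise.
#'
#' @param x a `reduced_matrix`.
#' @param baseline numeric vector from [baseline_mean()] (or any vector of
#'   per-tile reference values).
#' @param threshold positive calling threshold in log2 units; default 0.2.
#' @param merge merge adjacent same-direction called tiles (default TRUE).
#' @param samples optional subset of sample ids to call.
#' @return data.table of class `cna_calls`: `sample`, `chrom`, `start`,
#'   `end`, `delta` (length-weighted mean deviation), `direction`
#'   (`gain`/`loss`), `size_class`, `shared` (NA until [unique_shared()]),
#'   and `tiles` (list column of reduced-segment indices composing the
#'   call).
#' @export
call_differential <- function(x, baseline, threshold = 0.2, merge = TRUE,
                              samples = NULL) {
  if (!is.numeric(threshold) || threshold <= 0)
    validation_error("threshold must be > 0")
  if (length(baseline) != ncol(x$values))
    validation_error("baseline length does not match reduced matrix")
  samples <- samples %||% rownames(x$values)
  tiles <- x$segments
  out <- list()
  for (s in samples) {
    delta <- x$values[s, ] - baseline
    called <- !is.na(delta) & abs(delta) >= threshold
    if (!any(called)) next
    idx <- which(called)
    dir_sign <- sign(delta[idx])
    if (merge) {
      new_grp <- c(TRUE, !(idx[-1L] == idx[-length(idx)] + 1L &
                             tiles$chrom[idx[-1L]] == tiles$chrom[idx[-length(idx)]] &
                             tiles$start[idx[-1L]] == tiles$end[idx[-length(idx)]] &
                             dir_sign[-1L] == dir_sign[-length(idx)]))
      grp <- cumsum(new_grp)
    } else {
      grp <- seq_along(idx)
    }
    calls <- lapply(split(seq_along(idx), grp), function(k) {
      ti <- idx[k]
      len <- tiles$end[ti] - tiles$start[ti]
      data.table::data.table(
        sample = s, chrom = tiles$chrom[ti[1L]],
        start = tiles$start[ti[1L]], end = tiles$end[ti[length(ti)]],
        delta = sum(delta[ti] * len) / sum(len),
        direction = if (dir_sign[k[1L]] > 0) "gain" else "loss",
        tiles = list(ti))
    })
    out[[s]] <- data.table::rbindlist(calls)
  }
  calls <- if (length(out)) data.table::rbindlist(out) else
    data.table::data.table(sample = character(), chrom = character(),
                           start = double(), end = double(), delta = double(),
                           direction = character(), tiles = list())
  data.table::set(calls, j = "size_class",
                  value = size_class_of(calls$end - calls$start))
  data.table::set(calls, j = "shared", value = rep(NA, nrow(calls)))
  data.table::setattr(calls, "threshold", threshold)
  data.table::setattr(calls, "class",
                      c("cna_calls", class(calls)))
  calls
}

#' Count discrete CNA events per chromosome
#'
#' For one normalized profile (already log2 tumor/normal; windowed
#' low-pass output or a segmented profile), counts events per chromosome:
#' consecutive genomically adjacent windows/segments of the same
#' above-threshold direction merge into one event; sub-threshold or
#' missing stretches break events.  Chromosomes with no event report 0.
#'
#' @param profile a [sample_profile()], single-sample cohort, or segment
#'   data.frame with `chrom`, `start`, `end`, `log2`.
#' @param threshold positive log2 magnitude for an altered window;
#'   default 0.2.
#' @param chroms chromosomes to report; defaults to the build's
#'   chromosomes when available, else those present in the profile.
#' @return named integer vector chrom -> event count (including zeros).
#' @export
count_events_per_chromosome <- function(profile, threshold = 0.2,
                                        chroms = NULL) {
  segs <- as_profile_segments(profile)
  if (is.null(chroms)) {
    build <- if (is.list(profile) && !is.null(profile$build)) profile$build
             else if (inherits(profile, "segstack_cohort")) profile$build
    chroms <- if (!is.null(build)) names(build$chrom_lengths)
              else sort(unique(segs$chrom))
  }
  counts <- stats::setNames(integer(length(chroms)), chroms)
  for (ch in chroms) {
    sc <- segs[segs$chrom == ch]
    if (nrow(sc) == 0L) next
    sc <- sc[order(sc$start)]
    sgn <- ifelse(!is.finite(sc$log2), 0L,
                  ifelse(sc$log2 >= threshold, 1L,
                         ifelse(sc$log2 <= -threshold, -1L, 0L)))
    adj <- c(FALSE, sc$start[-1L] == sc$end[-nrow(sc)])
    new_event <- sgn != 0L & (!adj | c(TRUE, sgn[-1L] != sgn[-length(sgn)]))
    counts[ch] <- sum(new_event)
  }
  counts
}
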