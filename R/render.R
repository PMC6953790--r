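## Deterministic stacked SVG rendering of co-alteration query results:
## one horizontal bar per altered sample over a grey chromosome backbone,
## blue = copy loss, red = copy gain, query regions marked in black.

COL_LOSS <- "#2166ac"
COL_GAIN <- "#b2182b"
COL_BACKBONE <- "#c8c8c8"
COL_REGION <- "#1a1a1a"

svg_rect <- function(x, y, w, h, fill) {
  sprintf('<rect x="%.2f" y="%.2f" width="%.2f" height="%.2f" fill="%s"/>',
          x, y, w, h, fill)
}

svg_text <- function(x, y, s, size = 10) {
  sprintf('<text x="%.2f" y="%.2f" font-size="%d" font-family="sans-serif">%s</text>',
          x, y, size, s)
}

#' Render a stacked co-alteration plot as SVG
#'
#' Draws the classic stacked-segment view: a grey chromosome backbone, the
#' query region(s) as black ticks, and one horizontal bar per sample that
#' carries a qualifying alteration over either query region — blue bars
#' for losses, red for gains.  Rows are ordered losses before gains, then
#' by co-alteration category (`exclusive_a`, `exclusive_b`, `coincident`),
#' then by segment start; output is byte-identical for identical input.
#'
#' Bars are clipped to the view window.  Both query regions must lie on
#' one chromosome; for a cross-chromosome pair render one panel per
#' chromosome instead.
#'
#' @param summary a [cohort_summary()] result.
#' @param view optional numeric `c(start, end)` window in bp; defaults to
#'   the full chromosome when the cohort has a build, else the extent of
#'   the drawn segments padded by 5%.
#' @param width,row_height drawing geometry in px.
#' @param out optional file path; when given the SVG is also written there.
#' @return the SVG document as a single character string (invisibly when
#'   `out` is given).
#' @export
render_stack <- function(summary, view = NULL, width = 900, row_height = 8,
                         out = NULL) {
  if (!inherits(summary, "cairn_summary"))
    validation_error("render_stack expects a cohort_summary() result")
  q <- summary$query
  regions <- Filter(Negate(is.null), list(q$region_a, q$region_b))
  chroms <- unique(vapply(regions, `[[`, "", "chrom"))
  if (length(chroms) > 1L)
    validation_error(paste0(
      "query regions lie on different chromosomes; render one ",
      "per-chromosome panel for each region instead"))
  chr <- chroms[1L]
  segs <- summary$cohort$segments
  segs <- segs[segs$chrom == chr]
  hit <- rep(FALSE, nrow(segs))
  for (r in regions)
    hit <- hit | iv_overlaps(segs$start, segs$end, r$start, r$end)
  pass <- segs$log2 <= q$loss_threshold | segs$log2 >= q$gain_threshold
  bars <- segs[hit & pass]
  bars <- data.table::as.data.table(bars)
  data.table::set(bars, j = "dir",
                  value = ifelse(bars$log2 < 0, "loss", "gain"))
  cat_rank <- c(exclusive_a = 1L, exclusive_b = 2L, coincident = 3L, none = 4L)
  cats <- stats::setNames(summary$table$category, summary$table$sample)
  data.table::set(bars, j = "cat_r", value = cat_rank[cats[bars$sample]])
  data.table::setorderv(bars, c("dir", "cat_r", "start", "sample"),
                        order = c(-1L, 1L, 1L, 1L))  # loss < gain reversed sort
  if (is.null(view)) {
    view <- if (!is.null(summary$cohort$build)) {
      c(0, chrom_length(summary$cohort$build, chr))
    } else {
      ext <- range(c(bars$start, bars$end,
                     unlist(lapply(regions, function(r) c(r$start, r$end)))))
      pad <- 0.05 * diff(ext)
      c(max(0, ext[1L] - pad), ext[2L] + pad)
    }
  }
  x_of <- function(bp) (bp - view[1L]) / (view[2L] - view[1L]) * (width - 40) + 20
  n_rows <- nrow(bars)
  height <- 60 + n_rows * (row_height + 2)
  el <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
            as.integer(width), as.integer(height)),
    svg_text(20, 14, sprintf("chromosome %s [%s-%s bp]", chr,
                             format(view[1L], scientific = FALSE, trim = TRUE),
                             format(view[2L], scientific = FALSE, trim = TRUE))),
    svg_rect(x_of(view[1L]), 24, x_of(view[2L]) - x_of(view[1L]), 6,
             COL_BACKBONE))
  for (r in regions)
    el <- c(el, svg_rect(x_of(max(r$start, view[1L])), 20,
                         max(x_of(min(r$end, view[2L])) - x_of(max(r$start, view[1L])), 1),
                         14, COL_REGION))
  if (n_rows > 0L) {
    y <- 40 + (seq_len(n_rows) - 1L) * (row_height + 2)
    x0 <- x_of(pmax(bars$start, view[1L]))
    x1 <- x_of(pmin(bars$end, view[2L]))
    fill <- ifelse(bars$dir == "loss", COL_LOSS, COL_GAIN)
    el <- c(el, vapply(seq_len(n_rows), function(i) {
      svg_rect(x0[i], y[i], max(x1[i] - x0[i], 0.5), row_height, fill[i])
    }, character(1)))
  }
  el <- c(el, "</svg>")
  doc <- paste(el, collapse = "\n")
  if (!is.null(out)) {
    writeLines(doc, out)
    return(invisible(doc))
  }
  doc
}
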