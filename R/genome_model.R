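## Core data model: genome builds, annotation tracks, segment cohorts, and
## readers/writers for the SEG-style dialects emitted by common segmenters.
##
## Internal coordinate convention: 0-based half-open [start, end).  SEG /
## TCGA / HMMcopy-style files are 1-based inclusive on disk and are converted
## on input (start - 1) and back on output (start + 1); the conversion is
## self-inverse.  Chromosome labels are stored without a "chr" prefix.

#' Construct a genome build
#'
#' A genome build is a named set of chromosome lengths plus a free-text
#' build label (e.g. `"hg38"`, `"mm10"`, or a synthetic label).
#'
#' @param name free-text build label.
#' @param chrom_lengths named numeric vector, chromosome -> length in bp.
#'   Names are normalized with [norm_chrom()].
#' @return an object of class `genome_build`.
#' @examples
#' gb <- genome_build("toy", c(chr1 = 1e8, chr2 = 5e7))
#' gb$chrom_lengths[["1"]]
#' @export
genome_build <- function(name, chrom_lengths) {
  if (!is.character(name) || length(name) != 1L)
    validation_error("build name must be a single string")
  if (is.null(names(chrom_lengths)) || !all(nzchar(names(chrom_lengths))))
    validation_error("chrom_lengths must be a fully named vector")
  chrom_lengths <- vapply(chrom_lengths, as.double, numeric(1))
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0))
    validation_error("all chromosome lengths must be finite and > 0")
  names(chrom_lengths) <- norm_chrom(names(chrom_lengths))
  if (anyDuplicated(names(chrom_lengths)))
    validation_error("duplicate chromosome labels after normalization")
  structure(list(name = name, chrom_lengths = chrom_lengths),
            class = "genome_build")
}

#' @export
print.genome_build <- function(x, ...) {
  cat(sprintf("<genome_build> %s: %d chromosomes, %.1f Mb total\n",
              x$name, length(x$chrom_lengths), sum(x$chrom_lengths) / 1e6))
  invisible(x)
}

chrom_length <- function(build, chrom) {
  L <- build$chrom_lengths[norm_chrom(chrom)]
  if (anyNA(L))
    validation_error(sprintf("chromosome(s) not in build '%s': %s", build$name,
                             paste(unique(chrom[is.na(L)]), collapse = ", ")))
  unname(L)
}

## ---------------------------------------------------------------------------
## Cohort

SEG_COLS <- c("sample", "chrom", "start", "end", "log2")

normalize_segment_table <- function(segments) {
  dt <- data.table::as.data.table(segments)
  missing_cols <- setdiff(SEG_COLS, names(dt))
  if (length(missing_cols))
    validation_error(sprintf("segment table lacks column(s): %s",
                             paste(missing_cols, collapse = ", ")))
  if (!"n_markers" %in% names(dt)) dt[, n_markers := NA_integer_]
  dt <- dt[, c(SEG_COLS, "n_markers"), with = FALSE]
  dt[, `:=`(sample = as.character(sample), chrom = norm_chrom(chrom),
            start = as.double(start), end = as.double(end),
            log2 = as.double(log2), n_markers = as.integer(n_markers))]
  dt
}

validate_segments <- function(dt, build = NULL) {
  bad <- which(!is.finite(dt$start) | !is.finite(dt$end) | dt$start < 0 |
                 dt$end <= dt$start | !is.finite(dt$log2))
  if (length(bad))
    validation_error(sprintf(
      "invalid segment(s) at row(s) %s: need 0 <= start < end and finite log2",
      paste(utils::head(bad, 5L), collapse = ", ")))
  if (!is.null(build)) {
    unknown <- setdiff(unique(dt$chrom), names(build$chrom_lengths))
    if (length(unknown))
      validation_error(sprintf("chromosome(s) not in build '%s': %s",
                               build$name, paste(unknown, collapse = ", ")))
    L <- build$chrom_lengths[dt$chrom]
    oob <- which(dt$end > L)
    if (length(oob))
      validation_error(sprintf("segment(s) beyond chromosome end at row(s) %s",
                               paste(utils::head(oob, 5L), collapse = ", ")))
  }
  invisible(dt)
}

resolve_overlaps_mw <- function(dt) {
  ## collapse runs of mutually overlapping segments of one sample/chrom into
  ## a single segment with marker-weighted (fallback: length-weighted) mean
  out <- dt[, {
    o <- order(start)
    s <- start[o]; e <- end[o]; l2 <- log2[o]; nm <- n_markers[o]
    grp <- cumsum(c(1L, as.integer(s[-1L] >= cummax(e[-length(e)]))))
    data.table::rbindlist(lapply(split(seq_along(o), grp), function(ix) {
      w <- nm[ix]
      if (anyNA(w)) w <- e[ix] - s[ix]
      data.table::data.table(
        start = min(s[ix]), end = max(e[ix]),
        log2 = sum(l2[ix] * w) / sum(w),
        n_markers = if (anyNA(nm[ix])) NA_integer_
                    else as.integer(sum(nm[ix])))
    }))
  }, by = .(sample, chrom)]
  out[, c(SEG_COLS, "n_markers"), with = FALSE]
}

#' Construct a copy-number cohort
#'
#' A cohort is a set of per-sample segmented copy-number profiles on one
#' genome build.  Segments use 0-based half-open coordinates and carry a
#' log2 copy-number ratio (`0` = reference ploidy).
#'
#' @param segments data.frame with columns `sample`, `chrom`, `start`,
#'   `end`, `log2` and optionally `n_markers`.
#' @param build optional [genome_build()]; when given, segments are checked
#'   against chromosome bounds.
#' @param groups optional named character vector, sample -> group label.
#' @param overlap_action what to do when one sample has overlapping segments
#'   on a chromosome: `"error"` (default; overlap indicates corrupt input
#'   since segmenters emit disjoint segments) or `"marker_weighted_mean"`
#'   to merge overlapping runs.
#' @return object of class `segstack_cohort` with elements `segments`
#'   (a `data.table`, sorted by sample, chrom, start), `build`, `groups`.
#' @examples
#' co <- cohort(data.frame(sample = "s1", chrom = "1", start = 0, end = 100,
#'                         log2 = -0.5))
#' n_samples(co)
#' @export
cohort <- function(segments, build = NULL, groups = NULL,
                   overlap_action = c("error", "marker_weighted_mean")) {
  overlap_action <- match.arg(overlap_action)
  dt <- normalize_segment_table(segments)
  validate_segments(dt, build)
  data.table::setorder(dt, sample, chrom, start)
  has_overlap <- dt[, if (.N > 1L) any(start[-1L] < end[-.N]) else FALSE,
                    by = .(sample, chrom)]$V1
  if (any(has_overlap)) {
    if (overlap_action == "error")
      validation_error(paste0(
        "overlapping segments within one sample/chromosome; ",
        "use overlap_action = \"marker_weighted_mean\" to resolve"))
    dt <- resolve_overlaps_mw(dt)
    data.table::setorder(dt, sample, chrom, start)
  }
  if (!is.null(groups)) {
    groups <- stats::setNames(as.character(groups), names(groups))
    extra <- setdiff(names(groups), unique(dt$sample))
    groups <- groups[setdiff(names(groups), extra)]
  }
  structure(list(segments = dt, build = build, groups = groups),
            class = "segstack_cohort")
}

#' @export
print.segstack_cohort <- function(x, ...) {
  cat(sprintf("<segstack_cohort> %d samples, %d segments%s\n",
              n_samples(x), nrow(x$segments),
              if (is.null(x$build)) "" else paste0(" (", x$build$name, ")")))
  invisible(x)
}

#' Sample identifiers of a cohort
#' @param x a `segstack_cohort`.
#' @return character vector of unique sample ids, sorted.
#' @export
sample_ids <- function(x) sort(unique(x$segments$sample))

#' Number of samples in a cohort
#' @param x a `segstack_cohort`.
#' @export
n_samples <- function(x) length(unique(x$segments$sample))

#' Extract one sample's profile
#' @param x a `segstack_cohort`.
#' @param id sample identifier.
#' @return list with `sample_id`, `segments` (data.table), `group`, `build`.
#' @export
sample_profile <- function(x, id) {
  segs <- x$segments[sample == id]
  if (nrow(segs) == 0L && !id %in% x$segments$sample)
    validation_error(sprintf("unknown sample: %s", id))
  list(sample_id = id, segments = segs,
       group = if (!is.null(x$groups)) unname(x$groups[id]) else NA_character_,
       build = x$build)
}

## accept either a cohort (single- or multi-sample) or a sample_profile list
as_profile_segments <- function(profile) {
  if (inherits(profile, "segstack_cohort")) return(profile$segments)
  if (is.list(profile) && !is.null(profile$segments))
    return(data.table::as.data.table(profile$segments))
  normalize_segment_table(profile)
}

## ---------------------------------------------------------------------------
## Readers / writers

DIALECT_COLS <- list(
  seg = c(sample = "Sample", chrom = "Chromosome", start = "Start",
          end = "End", n_markers = "Num_Probes", log2 = "Segment_Mean"),
  tcga = c(sample = "Sample", chrom = "Chromosome", start = "Start",
           end = "End", n_markers = "Num_Probes", log2 = "Segment_Mean"),
  hmmcopy = c(chrom = "chr", start = "start", end = "end", state = "state",
              log2 = "median")
)

#' Read segmented copy-number profiles
#'
#' Parses SEG-style tab-delimited segment tables into a cohort.  Three
#' dialects are supported: `"seg"` (Sample/Chromosome/Start/End/
#' Num_Probes/Segment_Mean), `"tcga"` (the GDC PanCanAtlas segment-summary
#' flavour of the same layout; column names may be remapped via
#' `column_map` since they vary by release), and `"hmmcopy"` (per-merged-
#' segment output: chr/start/end/state/median, one sample per file).
#' All dialects are 1-based inclusive on disk and converted to the internal
#' 0-based half-open convention; `"chr"` prefixes are stripped.  Gzipped
#' files are read transparently.
#'
#' @param path file path (optionally gzipped).
#' @param dialect one of `"seg"`, `"tcga"`, `"hmmcopy"`.
#' @param build optional [genome_build()] used to validate chromosomes.
#' @param column_map optional named character vector remapping internal
#'   field names (`sample`, `chrom`, `start`, `end`, `log2`, `n_markers`)
#'   to the file's header names.
#' @param sample_id sample name for the `"hmmcopy"` dialect (which has no
#'   sample column); defaults to the file basename.
#' @param ... passed to [cohort()] (`groups`, `overlap_action`).
#' @return a `segstack_cohort`.
#' @export
read_segments <- function(path, dialect = c("seg", "tcga", "hmmcopy"),
                          build = NULL, column_map = NULL,
                          sample_id = NULL, ...) {
  dialect <- match.arg(dialect)
  cols <- DIALECT_COLS[[dialect]]
  if (!is.null(column_map)) cols[names(column_map)] <- column_map
  raw <- read_table_text(path, sep = "\t", header = TRUE,
                         colClasses = list(character = cols[["chrom"]]))
  need <- setdiff(unname(cols), c("Num_Probes", "state"))
  miss <- setdiff(need, names(raw))
  if (length(miss))
    parse_error(sprintf("%s: header lacks %s column(s) expected by dialect '%s'",
                        path, paste(miss, collapse = ", "), dialect))
  dt <- data.table::data.table(
    sample = if ("sample" %in% names(cols) && cols[["sample"]] %in% names(raw))
      as.character(raw[[cols[["sample"]]]])
    else rep(sample_id %||% sub("\\.(seg|txt|tsv)(\\.gz)?$", "", basename(path)),
             nrow(raw)),
    chrom = norm_chrom(raw[[cols[["chrom"]]]]),
    start = suppressWarnings(as.double(raw[[cols[["start"]]]])),
    end = suppressWarnings(as.double(raw[[cols[["end"]]]])),
    log2 = suppressWarnings(as.double(raw[[cols[["log2"]]]])))
  if ("n_markers" %in% names(cols) && cols[["n_markers"]] %in% names(raw))
    dt[, n_markers := suppressWarnings(as.integer(raw[[cols[["n_markers"]]]]))]
  ## line numbers are 1-based over the file, header is line 1
  bad <- which(!is.finite(dt$start) | !is.finite(dt$end) | is.na(dt$log2))
  if (length(bad))
    parse_error(sprintf("%s: non-numeric coordinate or segment mean at line(s) %s",
                        path, paste(utils::head(bad + 1L, 5L), collapse = ", ")))
  bad <- which(dt$end < dt$start)
  if (length(bad))
    parse_error(sprintf("%s: end < start at line(s) %s", path,
                        paste(utils::head(bad + 1L, 5L), collapse = ", ")))
  ## 1-based inclusive -> 0-based half-open
  dt[, start := start - 1]
  cohort(dt, build = build, ...)
}

#' Write a cohort as a SEG file
#'
#' Emits tab-delimited SEG (`Sample`, `Chromosome`, `Start`, `End`,
#' optionally `Num_Probes`, `Segment_Mean`), converting internal 0-based
#' half-open coordinates back to 1-based inclusive, so that
#' [read_segments()] inverts it exactly.
#'
#' @param x a `segstack_cohort`.
#' @param path output file path.
#' @param dialect only `"seg"` is supported for writing.
#' @export
write_segments <- function(x, path, dialect = "seg") {
  dialect <- match.arg(dialect, "seg")
  dt <- x$segments
  out <- data.table::data.table(
    Sample = dt$sample, Chromosome = dt$chrom,
    Start = format(dt$start + 1, scientific = FALSE, trim = TRUE),
    End = format(dt$end, scientific = FALSE, trim = TRUE))
  if (any(!is.na(dt$n_markers))) out[, Num_Probes := dt$n_markers]
  out[, Segment_Mean := dt$log2]
  ok <- tryCatch({
    data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) io_error(sprintf("cannot write %s: %s", path,
                                    conditionMessage(ok)))
  invisible(path)
}

## ---------------------------------------------------------------------------
## Annotation

#' Construct a genome annotation
#'
#' Bundles the feature tracks used by breakpoint classification: gene
#' spans (first exon start to last exon end, introns included), centromere
#' intervals, fragile/stable-site interval lists, an optional per-gene
#' expression table, and the telomere window width.  Telomeric windows are
#' derived per chromosome as `[0, W)` and `[L - W, L)` with
#' `W = telomere_window_bp`.
#'
#' @param build a [genome_build()].
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open); a derived `length` column is added.
#' @param centromeres data.frame `chrom`, `start`, `end` (at most one row
#'   per chromosome).
#' @param fragile_sites,stable_sites data.frames `chrom`, `start`, `end`.
#' @param expression named numeric vector, gene_id -> expression value.
#'   Genes absent from it simply have no expression (never imputed as 0).
#' @param telomere_window_bp window width in bp classifying a position as
#'   telomeric; default 2 Mb, matching the common tumor break-site rule.
#' @return object of class `genome_annotation`.
#' @export
genome_annotation <- function(build, genes = NULL, centromeres = NULL,
                              fragile_sites = NULL, stable_sites = NULL,
                              expression = NULL, telomere_window_bp = 2e6) {
  if (!inherits(build, "genome_build"))
    validation_error("build must be a genome_build")
  if (!is.numeric(telomere_window_bp) || telomere_window_bp <= 0)
    validation_error("telomere_window_bp must be > 0")
  tidy_track <- function(x, what, id_col = NULL) {
    if (is.null(x)) return(data.table::data.table(
      chrom = character(), start = double(), end = double()))
    dt <- data.table::as.data.table(x)
    dt[, chrom := norm_chrom(chrom)]
    dt[, `:=`(start = as.double(start), end = as.double(end))]
    unknown <- setdiff(unique(dt$chrom), names(build$chrom_lengths))
    if (length(unknown))
      validation_error(sprintf("%s on unknown chromosome(s): %s", what,
                               paste(unknown, collapse = ", ")))
    L <- build$chrom_lengths[dt$chrom]
    bad <- which(dt$start < 0 | dt$end <= dt$start | dt$end > L)
    if (length(bad)) {
      who <- if (!is.null(id_col)) dt[[id_col]][bad] else bad
      validation_error(sprintf("%s outside chromosome bounds: %s", what,
                               paste(utils::head(who, 5L), collapse = ", ")))
    }
    data.table::setorder(dt, chrom, start)
    dt
  }
  genes_dt <- if (is.null(genes)) {
    data.table::data.table(gene_id = character(), chrom = character(),
                           start = double(), end = double(), length = double())
  } else {
    g <- tidy_track(genes, "gene(s)", id_col = "gene_id")
    g[, gene_id := as.character(gene_id)]
    g[, length := end - start]
    g[, c("gene_id", "chrom", "start", "end", "length"), with = FALSE]
  }
  cen_dt <- tidy_track(centromeres, "centromere(s)")
  if (anyDuplicated(cen_dt$chrom))
    validation_error("more than one centromere interval on a chromosome")
  structure(list(
    build = build, genes = genes_dt, centromeres = cen_dt,
    fragile_sites = tidy_track(fragile_sites, "fragile site(s)"),
    stable_sites = tidy_track(stable_sites, "stable site(s)"),
    expression = expression, telomere_window_bp = telomere_window_bp),
    class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf(paste0("<genome_annotation> build %s: %d genes, %d centromeres, ",
                     "%d fragile, %d stable sites; telomere window %.1f Mb\n"),
              x$build$name, nrow(x$genes), nrow(x$centromeres),
              nrow(x$fragile_sites), nrow(x$stable_sites),
              x$telomere_window_bp / 1e6))
  invisible(x)
}

#' Telomeric windows of an annotation
#'
#' @param annotation a [genome_annotation()].
#' @return data.table `chrom`, `start`, `end` with two windows per
#'   chromosome (`[0, W)` and `[L - W, L)`), clipped and deduplicated for
#'   chromosomes shorter than `2 * W`.
#' @export
telomere_windows <- function(annotation) {
  W <- annotation$telomere_window_bp
  L <- annotation$build$chrom_lengths
  dt <- data.table::data.table(
    chrom = rep(names(L), each = 2L),
    start = as.vector(rbind(0, pmax(unname(L) - W, 0))),
    end = as.vector(rbind(pmin(W, unname(L)), unname(L))))
  unique(dt)
}

#' Look up a gene's region
#' @param annotation a [genome_annotation()].
#' @param gene_id gene identifier present in the annotation.
#' @return list with `chrom`, `start`, `end`, `id`.
#' @export
gene_region <- function(annotation, gene_id) {
  g <- annotation$genes[annotation$genes$gene_id == gene_id]
  if (nrow(g) == 0L)
    validation_error(sprintf("gene not in annotation: %s", gene_id))
  list(chrom = g$chrom[1L], start = g$start[1L], end = g$end[1L], id = gene_id)
}

#' Load a genome annotation from plain-text files
#'
#' @param chrom_lengths_path two-column TSV `chrom`, `length` (no header
#'   required; a header line is auto-detected).
#' @param genes_path BED-like 4+ column file: chrom, start (0-based), end,
#'   gene_id.
#' @param centromere_path optional TSV chrom, start, end.
#' @param fragile_path,stable_path optional BED interval files.
#' @param expression_path optional TSV gene_id, value.
#' @param build_name label for the resulting build.
#' @param telomere_window_bp telomere window width (default 2 Mb).
#' @return a [genome_annotation()].
#' @export
load_annotation <- function(chrom_lengths_path, genes_path = NULL,
                            centromere_path = NULL, fragile_path = NULL,
                            stable_path = NULL, expression_path = NULL,
                            build_name = "custom", telomere_window_bp = 2e6) {
  read_bedlike <- function(path, ids = FALSE) {
    if (is.null(path)) return(NULL)
    dt <- read_table_text(path, sep = "\t", header = FALSE)
    if (ncol(dt) < 3L + ids)
      parse_error(sprintf("%s: expected %d+ columns", path, 3L + ids))
    out <- data.table::data.table(chrom = as.character(dt[[1L]]),
                                  start = as.double(dt[[2L]]),
                                  end = as.double(dt[[3L]]))
    if (ids) out[, gene_id := as.character(dt[[4L]])]
    out
  }
  cl <- read_table_text(chrom_lengths_path, sep = "\t", header = FALSE)
  if (is.character(cl[[2L]])) cl <- cl[-1L]  # header line
  lens <- stats::setNames(as.double(cl[[2L]]), as.character(cl[[1L]]))
  build <- genome_build(build_name, lens)
  expr <- NULL
  if (!is.null(expression_path)) {
    e <- read_table_text(expression_path, sep = "\t", header = FALSE)
    if (is.character(e[[2L]])) e <- e[-1L]
    expr <- stats::setNames(as.double(e[[2L]]), as.character(e[[1L]]))
  }
  genome_annotation(build,
                    genes = read_bedlike(genes_path, ids = TRUE),
                    centromeres = read_bedlike(centromere_path),
                    fragile_sites = read_bedlike(fragile_path),
                    stable_sites = read_bedlike(stable_path),
                    expression = expr,
                    telomere_window_bp = telomere_window_bp)
}
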