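## Ground-truth synthetic cohorts: co-alteration compositions over a gene
## pair, drift experiments with planted unique/shared de novo events over
## a common ancestral profile, breakpoint placement biased toward feature
## tracks, and windowed tumor/normal low-pass profiles with planted
## per-chromosome events.  All generators draw one RNG stream per sample
## derived from (seed, sample id), so adding samples never perturbs the
## data of existing ones, and a fixed seed reproduces output byte for
## byte.

#' Default synthetic genome
#'
#' A small multi-chromosome genome sized so that planted events
#' (log-uniform lengths between 10 kb and 10 Mb) remain sparse.
#'
#' @param n_chrom number of chromosomes (default 5).
#' @param chrom_length length of each chromosome in bp (default 120 Mb).
#' @return a [genome_build()].
#' @export
sim_genome <- function(n_chrom = 5, chrom_length = 1.2e8) {
  genome_build("sim1", stats::setNames(rep(chrom_length, n_chrom),
                                       as.character(seq_len(n_chrom))))
}

## amplitude of a planted event: |log2| uniform on [lo, hi], random sign
draw_amplitude <- function(k, direction = NULL, lo = 0.3, hi = 1.0) {
  a <- stats::runif(k, lo, hi)
  s <- if (is.null(direction)) sign(stats::runif(k) - 0.5)
       else ifelse(direction == "gain", 1, -1)
  a * s
}

## event length: log-uniform over [10 kb, 10 Mb]
draw_length <- function(k, min_bp = 1e4, max_bp = 1e7) {
  round(exp(stats::runif(k, base::log(min_bp), base::log(max_bp))))
}

#' Simulate a co-alteration cohort
#'
#' Plants samples realizing an exact composition of co-alteration
#' categories over two query regions: `exclusive_a` samples carry a
#' qualifying segment over region A only, `exclusive_b` over B only,
#' `coincident` a single segment spanning both, and `none` either no
#' segment or a sub-threshold one (half of the `none` samples carry a
#' decoy at half the calling threshold so threshold logic is exercised).
#'
#' @param composition named integer vector with entries `exclusive_a`,
#'   `exclusive_b`, `coincident`, `none`.
#' @param region_a,region_b the two planted query regions; defaults put
#'   two 100 kb genes 20 Mb apart on chromosome 1 of [sim_genome()].
#' @param direction plant losses or gains (default `"loss"`).
#' @param genome a [genome_build()].
#' @param noise_sd Gaussian jitter s.d. added to every segment mean
#'   (default 0 = exact recovery).
#' @param seed RNG seed.
#' @return list with `cohort` (a `segstack_cohort`), `truth` (data.table
#'   `sample`, `category`), `region_a`, `region_b`.
#' @export
simulate_coalteration_cohort <- function(
    composition = c(exclusive_a = 10, exclusive_b = 5, coincident = 20,
                    none = 15),
    region_a = list(chrom = "1", start = 4.0e7, end = 4.01e7, id = "GENE_A"),
    region_b = list(chrom = "1", start = 6.0e7, end = 6.01e7, id = "GENE_B"),
    direction = c("loss", "gain"), genome = sim_genome(),
    noise_sd = 0, seed = 1L) {
  direction <- match.arg(direction)
  ra <- as_region(region_a)
  rb <- as_region(region_b)
  for (r in list(ra, rb))
    if (r$end > chrom_length(genome, r$chrom))
      validation_error("query region outside the synthetic genome")
  cats <- c("exclusive_a", "exclusive_b", "coincident", "none")
  if (!all(cats %in% names(composition)))
    validation_error("composition needs all four category counts")
  n_tot <- sum(composition[cats])
  ids <- sprintf("S%03d", seq_len(n_tot))
  truth <- data.table::data.table(
    sample = ids, category = rep(cats, composition[cats]))
  same_chrom <- ra$chrom == rb$chrom
  if (!same_chrom && any(composition["coincident"] > 0))
    validation_error("cross-chromosome regions cannot host single-segment coincident events")
  mag <- function() abs(draw_amplitude(1)) * (if (direction == "loss") -1 else 1)
  seg_for <- function(id, category) {
    with_stream(seed, id, {
      pad <- round(stats::runif(2, 1e4, 1e6))
      switch(category,
        exclusive_a = data.table::data.table(
          sample = id, chrom = ra$chrom,
          start = max(0, ra$start - pad[1L]),
          end = if (same_chrom) min(ra$end + pad[2L], rb$start - 1)
                else ra$end + pad[2L],
          log2 = mag()),
        exclusive_b = data.table::data.table(
          sample = id, chrom = rb$chrom,
          start = if (same_chrom) max(rb$start - pad[1L], ra$end + 1)
                  else max(0, rb$start - pad[1L]),
          end = rb$end + pad[2L], log2 = mag()),
        coincident = data.table::data.table(
          sample = id, chrom = ra$chrom,
          start = max(0, min(ra$start, rb$start) - pad[1L]),
          end = max(ra$end, rb$end) + pad[2L], log2 = mag()),
        none = if (stats::runif(1) < 0.5) NULL else data.table::data.table(
          sample = id, chrom = ra$chrom,
          start = max(0, ra$start - pad[1L]), end = ra$end + pad[2L],
          log2 = 0.1 * (if (direction == "loss") -1 else 1)))
    })
  }
  segs <- data.table::rbindlist(Filter(Negate(is.null),
                                       mapply(seg_for, truth$sample,
                                              truth$category,
                                              SIMPLIFY = FALSE)))
  if (noise_sd > 0) {
    noise <- unlist(lapply(unique(segs$sample), function(id)
      with_stream(seed + 1L, id,
                  stats::rnorm(sum(segs$sample == id), 0, noise_sd))))
    data.table::set(segs, j = "log2", value = segs$log2 + noise)
  }
  ## samples with no segments still belong to the cohort: give each an
  ## explicitly neutral whole-chromosome segment so n_samples is exact
  absent <- setdiff(ids, unique(segs$sample))
  if (length(absent))
    segs <- data.table::rbindlist(list(segs, data.table::data.table(
      sample = absent, chrom = ra$chrom, start = 0,
      end = chrom_length(genome, ra$chrom), log2 = 0)))
  list(cohort = cohort(segs, build = genome), truth = truth,
       region_a = ra, region_b = rb)
}

## place k mutually disjoint intervals on the genome, avoiding `occupied`
## (data.table chrom/start/end); simple rejection sampling
place_disjoint <- function(k, genome, occupied, max_try = 2000L,
                           weights = NULL, tracks = NULL) {
  L <- genome$chrom_lengths
  out <- data.table::data.table(chrom = character(), start = double(),
                                end = double())
  lens <- draw_length(k)
  for (i in seq_len(k)) {
    placed <- FALSE
    for (try in seq_len(max_try)) {
      if (!is.null(weights) && !is.null(tracks) &&
          stats::runif(1) < weights / (weights + 1)) {
        ## biased placement: anchor the start inside a random track interval
        tr <- tracks[sample.int(nrow(tracks), 1L)]
        ch <- tr$chrom
        st <- floor(stats::runif(1, tr$start, tr$end))
      } else {
        ch <- sample(names(L), 1L, prob = L / sum(L))
        st <- floor(stats::runif(1, 0, L[[ch]] - lens[i] + 1))
      }
      en <- st + lens[i]
      if (en > L[[ch]]) next
      busy <- rbind(occupied, out)
      clash <- busy$chrom == ch & iv_overlaps(busy$start, busy$end, st, en)
      if (!any(clash)) {
        out <- rbind(out, data.table::data.table(chrom = ch, start = st,
                                                 end = en))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      validation_error("could not place disjoint events; genome too crowded")
  }
  out
}

## overlay an event (interval + delta) onto a sample's segment table
apply_event <- function(segs, ev_chrom, ev_start, ev_end, delta) {
  on <- segs$chrom == ev_chrom &
    iv_overlaps(segs$start, segs$end, ev_start, ev_end)
  keep <- segs[!on]
  pieces <- lapply(which(on), function(i) {
    s <- segs[i]
    parts <- list()
    if (s$start < ev_start)
      parts <- c(parts, list(data.table::data.table(
        sample = s$sample, chrom = s$chrom, start = s$start, end = ev_start,
        log2 = s$log2)))
    parts <- c(parts, list(data.table::data.table(
      sample = s$sample, chrom = s$chrom,
      start = max(s$start, ev_start), end = min(s$end, ev_end),
      log2 = s$log2 + delta)))
    if (s$end > ev_end)
      parts <- c(parts, list(data.table::data.table(
        sample = s$sample, chrom = s$chrom, start = ev_end, end = s$end,
        log2 = s$log2)))
    data.table::rbindlist(parts)
  })
  out <- data.table::rbindlist(c(list(keep[, c("sample", "chrom", "start",
                                               "end", "log2"), with = FALSE]),
                                 pieces))
  data.table::setorder(out, chrom, start)
  out
}

#' Simulate a serial-passage drift experiment
#'
#' Emulates a passaging experiment: every sample inherits one common
#' ancestral segmented profile (whole-genome coverage with a few fixed
#' ancestral CNAs); each non-control sample then acquires
#' `Poisson(unique_rate)` private de novo events, each non-control group
#' acquires `Poisson(shared_rate)` events copied into >= 2 of its
#' samples, and controls acquire `Poisson(control_rate)` private events.
#' Events are mutually disjoint across the cohort and avoid the
#' ancestral CNAs, with log-uniform lengths in [10 kb, 10 Mb] and
#' amplitudes of +/- 0.3 to 1.0 log2 units for perturbed samples.
#' Optionally, breakpoint placement can be biased toward a feature track.
#'
#' Because the "normal" reference downstream is the *mean of the
#' controls*, a control-group event of amplitude `a` carried by `k` of
#' `m` controls shifts the baseline by `k*a/m` and therefore mirrors
#' into every non-carrier sample as a deviation of `-k*a/m`.  The
#' generator keeps this self-referential geometry exactly predictable:
#' control private events draw `|a|` from [0.3, 0.75] (carrier deviation
#' `0.75*a >= 0.225`, called; mirror `a/4 <= 0.1875`, silent), and
#' control shared events are planted in exactly 2 of 4 controls with
#' `|a|` in [0.45, 0.75] (both carriers and both non-carriers deviate by
#' `a/2 >= 0.225`, so one such event is recovered as 4 shared control
#' calls plus one mirror call in every sample outside the control
#' group).  At zero jitter the expected differential-call table is thus
#' an exact function of the planted truth; see the methods vignette.
#'
#' @param groups named integer vector group -> number of samples; default
#'   three groups of four isolates (one control + two perturbed), the
#'   usual design for this assay.
#' @param control_group name of the control group.
#' @param unique_rate expected private events per perturbed sample
#'   (default 12).
#' @param shared_rate expected shared events per perturbed group
#'   (default 2); each is carried by 2 to all samples of the group.
#' @param control_rate expected private events per control sample
#'   (default 3).
#' @param control_shared_rate expected shared events within the control
#'   group (default 2).
#' @param jitter_sd Gaussian jitter s.d. on every final segment mean
#'   (default 0.02; set 0 for exact recovery).
#' @param genome a [genome_build()].
#' @param bias_tracks optional data.table `chrom`, `start`, `end`; with
#'   `bias_weight > 0`, event starts are anchored inside these intervals
#'   with probability `bias_weight / (bias_weight + 1)`.
#' @param bias_weight relative placement weight for `bias_tracks`.
#' @param shared_in_all if `TRUE`, shared events of perturbed groups are
#'   carried by every sample of the group (genotype-driven recurrent
#'   events) instead of a random subset of >= 2; gives the clean
#'   within-group-similar geometry expected of clonal group signals.
#' @param seed RNG seed.
#' @return list with `cohort` (grouped `segstack_cohort`), `truth`
#'   (data.table of planted events: `sample`, `chrom`, `start`, `end`,
#'   `delta`, `kind` = unique/shared) and `groups`.
#' @export
simulate_drift_experiment <- function(
    groups = c(ctrl = 4L, kd_a = 4L, kd_b = 4L), control_group = "ctrl",
    unique_rate = 12, shared_rate = 2, control_rate = 3,
    control_shared_rate = 2, jitter_sd = 0.02, genome = sim_genome(),
    bias_tracks = NULL, bias_weight = 0, shared_in_all = FALSE,
    seed = 1L) {
  if (!control_group %in% names(groups))
    validation_error("control_group must be one of the groups")
  ids <- unlist(lapply(names(groups), function(g)
    sprintf("%s_%d", g, seq_len(groups[[g]]))))
  grp <- stats::setNames(rep(names(groups), unlist(groups)), ids)
  ## common ancestral profile: whole-genome neutral coverage plus a few
  ## fixed ancestral CNAs (exercises the reduction on non-trivial input)
  L <- genome$chrom_lengths
  base_segs <- data.table::data.table(
    sample = "template", chrom = names(L), start = 0, end = unname(L),
    log2 = 0)
  anc <- with_stream(seed, "ancestral", {
    a <- place_disjoint(3L, genome,
                        data.table::data.table(chrom = character(),
                                               start = double(),
                                               end = double()))
    data.table::set(a, j = "delta", value = draw_amplitude(nrow(a)))
    a
  })
  for (i in seq_len(nrow(anc)))
    base_segs <- apply_event(base_segs, anc$chrom[i], anc$start[i],
                             anc$end[i], anc$delta[i])
  ## plant events; keep all events cohort-wide disjoint
  occupied <- anc[, c("chrom", "start", "end"), with = FALSE]
  truth <- list()
  events_by_sample <- stats::setNames(
    rep(list(data.table::data.table(chrom = character(), start = double(),
                                    end = double(), delta = double())), length(ids)),
    ids)
  for (g in names(groups)) {
    g_ids <- ids[grp[ids] == g]
    is_ctrl <- g == control_group
    s_rate <- if (is_ctrl) control_shared_rate else shared_rate
    u_rate <- if (is_ctrl) control_rate else unique_rate
    ## shared events for the group
    sh <- with_stream(seed, paste0("shared_", g), {
      n_sh <- stats::rpois(1, s_rate)
      if (n_sh > 0) {
        ev <- place_disjoint(n_sh, genome, occupied,
                             weights = bias_weight, tracks = bias_tracks)
        amp <- if (is_ctrl) draw_amplitude(n_sh, lo = 0.45, hi = 0.75)
               else draw_amplitude(n_sh)
        data.table::set(ev, j = "delta", value = amp)
        carriers <- lapply(seq_len(n_sh), function(i) {
          if (!is_ctrl && shared_in_all) return(sort(g_ids))
          k <- if (is_ctrl) 2L else sample(2:length(g_ids), 1L)
          sort(sample(g_ids, k))
        })
        list(ev = ev, carriers = carriers)
      } else NULL
    })
    if (!is.null(sh)) {
      occupied <- rbind(occupied,
                        sh$ev[, c("chrom", "start", "end"), with = FALSE])
      for (i in seq_len(nrow(sh$ev))) {
        for (s in sh$carriers[[i]])
          events_by_sample[[s]] <- rbind(events_by_sample[[s]], sh$ev[i, ])
        truth[[length(truth) + 1L]] <- data.table::data.table(
          sample = sh$carriers[[i]], chrom = sh$ev$chrom[i],
          start = sh$ev$start[i], end = sh$ev$end[i],
          delta = sh$ev$delta[i], kind = "shared", group = g)
      }
    }
    ## private events per sample
    for (s in g_ids) {
      ev <- with_stream(seed, paste0("unique_", s), {
        n_u <- stats::rpois(1, u_rate)
        if (n_u > 0) {
          e <- place_disjoint(n_u, genome, occupied,
                              weights = bias_weight, tracks = bias_tracks)
          amp <- if (is_ctrl) draw_amplitude(n_u, hi = 0.75)
                 else draw_amplitude(n_u)
          data.table::set(e, j = "delta", value = amp)
          e
        } else NULL
      })
      if (!is.null(ev)) {
        occupied <- rbind(occupied,
                          ev[, c("chrom", "start", "end"), with = FALSE])
        events_by_sample[[s]] <- rbind(events_by_sample[[s]], ev)
        truth[[length(truth) + 1L]] <- data.table::data.table(
          sample = s, chrom = ev$chrom, start = ev$start, end = ev$end,
          delta = ev$delta, kind = "unique", group = g)
      }
    }
  }
  ## materialize per-sample profiles
  segs <- data.table::rbindlist(lapply(ids, function(s) {
    prof <- data.table::copy(base_segs)
    data.table::set(prof, j = "sample", value = s)
    ev <- events_by_sample[[s]]
    for (i in seq_len(nrow(ev)))
      prof <- apply_event(prof, ev$chrom[i], ev$start[i], ev$end[i],
                          ev$delta[i])
    if (jitter_sd > 0) {
      jit <- with_stream(seed + 2L, s, stats::rnorm(nrow(prof), 0, jitter_sd))
      data.table::set(prof, j = "log2", value = prof$log2 + jit)
    }
    prof
  }))
  truth_dt <- if (length(truth)) data.table::rbindlist(truth) else
    data.table::data.table(sample = character(), chrom = character(),
                           start = double(), end = double(),
                           delta = double(), kind = character(),
                           group = character())
  list(cohort = cohort(segs, build = genome, groups = grp),
       truth = truth_dt, groups = grp)
}

#' Simulate a windowed tumor/normal low-pass profile
#'
#' Emulates shallow-coverage window counts after normalization: a tumor
#' profile of fixed-width windows (default 500 kb, the usual bin for
#' 1000–2000 reads per window) carrying `events_per_chrom` planted
#' events per chromosome with |log2| >= 0.2, plus Gaussian window noise,
#' and a matched normal profile centered at 0.
#'
#' @param events_per_chrom integer (recycled) or named vector: planted
#'   events per chromosome.  Events are separated by at least one neutral
#'   window so the planted count is identifiable.
#' @param genome a [genome_build()].
#' @param window_bp window width (default 5e5).
#' @param magnitude_range |log2| amplitude range of planted events
#'   (default `c(0.3, 1)`).
#' @param noise_sd Gaussian window noise s.d. (default 0.05).
#' @param seed RNG seed.
#' @return list with `tumor` and `normal` (single-sample
#'   `segstack_cohort`s of windows) and `truth` (data.table `chrom`,
#'   `start`, `end`, `delta`).
#' @export
simulate_windowed_profile <- function(events_per_chrom = 2L,
                                      genome = sim_genome(),
                                      window_bp = 5e5,
                                      magnitude_range = c(0.3, 1),
                                      noise_sd = 0.05, seed = 1L) {
  L <- genome$chrom_lengths
  k_chrom <- if (is.null(names(events_per_chrom))) {
    stats::setNames(rep(as.integer(events_per_chrom), length(L))[seq_along(L)],
                    names(L))
  } else {
    ks <- stats::setNames(integer(length(L)), names(L))
    ks[norm_chrom(names(events_per_chrom))] <- as.integer(events_per_chrom)
    ks
  }
  windows <- data.table::rbindlist(lapply(names(L), function(ch) {
    starts <- seq(0, L[[ch]] - window_bp, by = window_bp)
    data.table::data.table(chrom = ch, start = starts,
                           end = starts + window_bp)
  }))
  truth <- list()
  signal <- numeric(nrow(windows))
  for (ch in names(L)) {
    k <- k_chrom[[ch]]
    if (k == 0L) next
    idx <- which(windows$chrom == ch)
    n_win <- length(idx)
    planted <- with_stream(seed, paste0("events_", ch), {
      ## choose k runs of windows separated by >= 1 neutral window
      run_len <- sample(2:6, k, replace = TRUE)
      while (sum(run_len) + (k - 1L) > n_win - 2L)
        run_len <- pmax(run_len - 1L, 1L)
      free <- n_win - sum(run_len) - (k - 1L)
      gaps <- if (k > 0) {
        cuts <- sort(sample.int(free + k, k)) # stars-and-bars
        c(cuts[1L] - 1L, diff(cuts) - 1L)
      } else integer()
      starts <- cumsum(c(1L, utils::head(run_len, -1L) + 1L)) + cumsum(gaps)
      amp <- stats::runif(k, magnitude_range[1L], magnitude_range[2L]) *
        sign(stats::runif(k) - 0.5)
      list(starts = starts, run_len = run_len, amp = amp)
    })
    for (i in seq_len(k)) {
      wi <- idx[planted$starts[i]:(planted$starts[i] + planted$run_len[i] - 1L)]
      signal[wi] <- planted$amp[i]
      truth[[length(truth) + 1L]] <- data.table::data.table(
        chrom = ch, start = windows$start[wi[1L]],
        end = windows$end[wi[length(wi)]], delta = planted$amp[i])
    }
  }
  noise_t <- with_stream(seed, "tumor_noise",
                         stats::rnorm(nrow(windows), 0, noise_sd))
  noise_n <- with_stream(seed, "normal_noise",
                         stats::rnorm(nrow(windows), 0, noise_sd))
  mk <- function(id, vals) {
    dt <- data.table::copy(windows)
    data.table::set(dt, j = "sample", value = id)
    data.table::set(dt, j = "log2", value = vals)
    cohort(dt, build = genome)
  }
  truth_dt <- if (length(truth)) data.table::rbindlist(truth) else
    data.table::data.table(chrom = character(), start = double(),
                           end = double(), delta = double())
  list(tumor = mk("tumor", signal + noise_t),
       normal = mk("normal", noise_n), truth = truth_dt)
}
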