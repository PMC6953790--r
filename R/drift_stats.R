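## Genetic-drift statistics over reduced-segment profiles: Euclidean
## distances, average-linkage clustering, unique-versus-shared event
## tabulation, and the Fisher's-exact comparison of event randomness
## between groups.

#' Euclidean distance matrix over reduced-segment profiles
#'
#' Pairwise Euclidean distance between samples' reduced-segment log2
#' vectors, the drift measure for serially passaged isolates.  With
#' `relative_to_baseline = TRUE` the vectors are first re-expressed as
#' deviations from the control mean; since a constant shift cancels in
#' pairwise differences over shared tiles, both modes agree wherever the
#' same tiles are compared, and both are exposed.
#'
#' Missing tiles are handled pairwise-complete: a tile missing in either
#' sample of a pair is dropped for that pair.  The number of tiles
#' actually compared is attached as `attr(, "n_complete")` so distances
#' can be judged comparable.
#'
#' @param x a `reduced_matrix` with at least two samples.
#' @param relative_to_baseline subtract the control-mean baseline first.
#' @param control_ids control sample ids (required when
#'   `relative_to_baseline = TRUE`).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(x, relative_to_baseline = FALSE,
                            control_ids = NULL) {
  V <- x$values
  if (nrow(V) < 2L) validation_error("need at least 2 samples for distances")
  if (relative_to_baseline) {
    if (is.null(control_ids))
      validation_error("relative_to_baseline = TRUE needs control_ids")
    V <- sweep(V, 2L, baseline_mean(x, control_ids))
  }
  n <- nrow(V)
  D <- matrix(0, n, n, dimnames = list(rownames(V), rownames(V)))
  NC <- matrix(ncol(V), n, n, dimnames = dimnames(D))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(V[i, ]) & !is.na(V[j, ])
      d <- sqrt(sum((V[i, ok] - V[j, ok])^2))
      D[i, j] <- D[j, i] <- d
      NC[i, j] <- NC[j, i] <- sum(ok)
    }
  }
  attr(D, "n_complete") <- NC
  D
}

#' Average-linkage hierarchical clustering of samples
#'
#' Agglomerative clustering of a sample distance matrix.  Samples are
#' ordered lexicographically by id before clustering so that merge order
#' (and hence leaf order) is deterministic under distance ties.
#'
#' @param D symmetric distance matrix (e.g. from [distance_matrix()]).
#' @param method linkage passed to [stats::hclust()]; default
#'   `"average"` (UPGMA).
#' @return object of class `drift_clustering`: `hclust` (the merge tree;
#'   heights are merge distances), `leaf_order` (labels left to right),
#'   `method`.
#' @export
hierarchical_cluster <- function(D, method = "average") {
  labs <- sort(rownames(D))
  D <- D[labs, labs]
  hc <- stats::hclust(stats::as.dist(D), method = method)
  structure(list(hclust = hc, leaf_order = hc$labels[hc$order],
                 method = method),
            class = "drift_clustering")
}

#' Cut a drift clustering into k groups
#' @param x a `drift_clustering`.
#' @param k number of clusters.
#' @return named integer vector sample -> cluster.
#' @export
cut_clusters <- function(x, k) stats::cutree(x$hclust, k = k)

#' Write a drift clustering as a Newick tree
#'
#' Branch lengths are derived from merge heights (ultrametric tree).
#'
#' @param x a `drift_clustering`.
#' @param path optional output file.
#' @return the Newick string (invisibly when `path` is given).
#' @export
cluster_newick <- function(x, path = NULL) {
  phy <- ape::as.phylo(x$hclust)
  s <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Tabulate unique versus shared CNA calls
#'
#' A call is *shared* when at least one of its reduced segments is called
#' in the same direction in two or more in-scope samples (the same lesion
#' recurring across isolates is potentially non-random); otherwise it is
#' *unique* to its sample.  Counts are tallied per call occurrence, so
#' `unique + shared` equals the number of in-scope calls.
#'
#' @param calls a `cna_calls` table from [call_differential()] (one
#'   reduced-segment frame).
#' @param samples_in_scope samples over which sharedness is evaluated;
#'   default all samples present in `calls`.  Pass a group's samples to
#'   evaluate sharedness within the comparison group, or all cohort
#'   samples to evaluate across the cohort.
#' @return list with `unique`, `shared` (counts over in-scope calls) and
#'   `calls` (the in-scope calls with the `shared` column filled in).
#' @export
unique_shared <- function(calls, samples_in_scope = NULL) {
  samples_in_scope <- samples_in_scope %||% unique(calls$sample)
  sc <- calls[calls$sample %in% samples_in_scope]
  if (nrow(sc) == 0L)
    return(list(unique = 0L, shared = 0L, calls = sc))
  occ <- data.table::rbindlist(lapply(seq_len(nrow(sc)), function(i) {
    data.table::data.table(call_id = i, sample = sc$sample[i],
                           direction = sc$direction[i],
                           tile = sc$tiles[[i]])
  }))
  ## per (tile, direction): number of distinct in-scope samples calling it
  n_samp <- occ[, list(n = data.table::uniqueN(sample)),
                by = c("tile", "direction")]
  occ <- merge(occ, n_samp, by = c("tile", "direction"))
  shared_ids <- unique(occ$call_id[occ$n >= 2L])
  sc <- data.table::copy(sc)
  data.table::set(sc, j = "shared",
                  value = seq_len(nrow(sc)) %in% shared_ids)
  list(unique = sum(!sc$shared), shared = sum(sc$shared), calls = sc)
}

#' Fisher's exact comparison of unique/shared composition
#'
#' Two-sided Fisher's exact test on the 2x2 table
#' `rbind(c(unique_a, shared_a), c(unique_b, shared_b))`, the randomness
#' comparison between two groups' CNA repertoires.  The p-value follows
#' the conventional point-probability rule: the sum of probabilities of
#' all tables (fixed margins, hypergeometric) no more probable than the
#' observed one.  The odds ratio is the sample odds ratio
#' `(unique_a * shared_b) / (shared_a * unique_b)`.
#'
#' @param group_a,group_b length-2 numeric vectors `c(unique, shared)`.
#' @return list with `odds_ratio`, `p_value` and `table`.
#' @export
fisher_randomness <- function(group_a, group_b) {
  tab <- rbind(as.double(group_a), as.double(group_b))
  if (any(tab < 0) || any(!is.finite(tab)) || any(tab != round(tab)))
    validation_error("counts must be non-negative integers")
  if (all(tab == 0)) validation_error("all-zero table")
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  or <- (a * d) / (b * c_)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate 2x2 table (zero margin); p = 1")
    return(list(odds_ratio = or, p_value = 1, table = tab))
  }
  r1 <- a + b; c1 <- a + c_; N <- sum(tab)
  xs <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- stats::dhyper(xs, c1, N - c1, r1)
  p_obs <- stats::dhyper(a, c1, N - c1, r1)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  list(odds_ratio = or, p_value = p, table = tab)
}

#' One-call drift summary for a grouped cohort
#'
#' Convenience wrapper computing, from a reduced matrix and its
#' differential calls, the full drift picture: distance matrix,
#' average-linkage clustering, per-group unique/shared counts and ratios,
#' and pairwise Fisher's exact tests between groups.  A group with zero
#' shared calls gets an undefined (`NA`) ratio rather than infinity.
#'
#' @param x a `reduced_matrix`.
#' @param calls a `cna_calls` table over `x`.
#' @param groups named character vector sample -> group label.
#' @param control_ids optional controls for baseline-relative distances.
#' @param scope `"group"` (default; sharedness evaluated within each
#'   group) or `"cohort"` (across all samples in `calls`).
#' @return object of class `drift_result`.
#' @export
drift_summary <- function(x, calls, groups, control_ids = NULL,
                          scope = c("group", "cohort")) {
  scope <- match.arg(scope)
  D <- distance_matrix(x, relative_to_baseline = !is.null(control_ids),
                       control_ids = control_ids)
  clust <- hierarchical_cluster(D)
  glabs <- sort(unique(groups))
  us <- lapply(glabs, function(g) {
    ids <- names(groups)[groups == g]
    in_scope <- if (scope == "group") ids else unique(calls$sample)
    r <- unique_shared(calls, samples_in_scope = in_scope)
    if (scope == "cohort") {
      keep <- r$calls$sample %in% ids
      r$unique <- sum(!r$calls$shared[keep])
      r$shared <- sum(r$calls$shared[keep])
      r$calls <- r$calls[keep]
    }
    r
  })
  names(us) <- glabs
  counts <- data.table::data.table(
    group = glabs,
    unique = vapply(us, function(r) as.integer(r$unique), integer(1)),
    shared = vapply(us, function(r) as.integer(r$shared), integer(1)))
  data.table::set(counts, j = "ratio",
                  value = ifelse(counts$shared > 0,
                                 counts$unique / counts$shared, NA_real_))
  fisher <- list()
  if (length(glabs) > 1L) {
    pairs <- utils::combn(glabs, 2L, simplify = FALSE)
    fisher <- lapply(pairs, function(p) {
      ca <- counts[counts$group == p[1L]]
      cb <- counts[counts$group == p[2L]]
      ft <- fisher_randomness(c(ca$unique, ca$shared), c(cb$unique, cb$shared))
      list(group_a = p[1L], group_b = p[2L],
           odds_ratio = ft$odds_ratio, p_value = ft$p_value)
    })
  }
  structure(list(distance_matrix = D, clustering = clust,
                 unique_shared = counts, fisher_tests = fisher,
                 calls_by_group = us, scope = scope),
            class = "drift_result")
}

#' @export
print.drift_result <- function(x, ...) {
  cat(sprintf("<drift_result> %d samples, sharedness scope: %s\n",
              nrow(x$distance_matrix), x$scope))
  print(x$unique_shared)
  for (ft in x$fisher_tests)
    cat(sprintf("  %s vs %s: OR = %.3g, p = %.3g\n", ft$group_a, ft$group_b,
                ft$odds_ratio, ft$p_value))
  invisible(x)
}
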