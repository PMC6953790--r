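mk_matrix <- function(values) {
  ## wrap a plain samples x tiles matrix (one chromosome, 1 kb tiles)
  n_tiles <- ncol(values)
  structure(list(
    values = values,
    segments = data.table::data.table(chrom = "1",
                                      start = (seq_len(n_tiles) - 1) * 1e3,
                                      end = seq_len(n_tiles) * 1e3),
    boundaries = list(`1` = seq(0, n_tiles * 1e3, by = 1e3))),
    class = "reduced_matrix")
}

test_that("distance_matrix: identities, closed form, brute-force oracle", {
  V <- rbind(a = rep(0, 10), b = rep(0, 10))
  expect_equal(distance_matrix(mk_matrix(V))["a", "b"], 0)

  ## +0.3 on exactly 4 tiles -> sqrt(4 * 0.09) = 0.6
  V <- rbind(a = rep(0, 10), b = c(rep(0.3, 4), rep(0, 6)))
  expect_equal(distance_matrix(mk_matrix(V))["a", "b"], 0.6)

  ## random matrices vs an independent sum-of-squares oracle
  set.seed(21)
  for (rep in 1:3) {
    V <- matrix(rnorm(5 * 50), nrow = 5,
                dimnames = list(paste0("s", 1:5), NULL))
    V[sample(length(V), 20)] <- NA
    D <- distance_matrix(mk_matrix(V))
    for (i in 1:4) for (j in (i + 1):5) {
      ss <- 0; nc <- 0
      for (t in 1:50) {
        if (!is.na(V[i, t]) && !is.na(V[j, t])) {
          ss <- ss + (V[i, t] - V[j, t])^2
          nc <- nc + 1
        }
      }
      expect_equal(as.numeric(D[i, j]), as.numeric(sqrt(ss)))
      expect_equal(as.numeric(attr(D, "n_complete")[i, j]), nc)
    }
    ## symmetry, zero diagonal, triangle inequality on complete tiles
    expect_equal(D, t(D), ignore_attr = TRUE)
    expect_equal(unname(diag(D)), rep(0, 5))
  }

  ## baseline-relative mode shifts by the control mean
  V <- rbind(c1 = rep(0.4, 6), s = rep(0, 6))
  Dr <- distance_matrix(mk_matrix(V), relative_to_baseline = TRUE,
                        control_ids = "c1")
  expect_equal(Dr["c1", "s"], sqrt(6 * 0.16))
  expect_error(distance_matrix(mk_matrix(V[1, , drop = FALSE])),
               class = "segstack_validation_error")
})

test_that("triangle inequality holds over complete random matrices", {
  set.seed(7)
  V <- matrix(rnorm(6 * 40), nrow = 6,
              dimnames = list(paste0("s", 1:6), NULL))
  D <- distance_matrix(mk_matrix(V))
  for (i in 1:6) for (j in 1:6) for (k in 1:6)
    expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
})

test_that("hierarchical clustering is deterministic and recovers groups", {
  ## 2 samples: single merge at their distance
  V <- rbind(a = c(0, 0), b = c(0.3, 0.3))
  cl <- hierarchical_cluster(distance_matrix(mk_matrix(V)))
  expect_equal(cl$hclust$height, sqrt(2 * 0.09))
  expect_setequal(cl$leaf_order, c("a", "b"))

  ## planted two-group structure (within-group drift << between-group,
  ## i.e. group-shared events dominate private ones) is recovered at k = 2
  d <- simulate_drift_experiment(
    groups = c(ctrl = 4L, kd = 4L), unique_rate = 2, shared_rate = 10,
    control_rate = 1, control_shared_rate = 0, shared_in_all = TRUE,
    seed = 13)
  rm_ <- reduce_segments(d$cohort)
  D <- distance_matrix(rm_)
  cl2 <- hierarchical_cluster(D)
  k2 <- cut_clusters(cl2, 2)
  expect_equal(length(unique(k2[grep("^ctrl", names(k2))])), 1L)
  expect_equal(length(unique(k2[grep("^kd", names(k2))])), 1L)
  expect_true(k2[["ctrl_1"]] != k2[["kd_1"]])

  ## permuting the sample order leaves merge heights unchanged
  perm <- sample(rownames(D))
  cl3 <- hierarchical_cluster(D[perm, perm])
  expect_equal(cl3$hclust$height, cl2$hclust$height)
  expect_equal(cl3$leaf_order, cl2$leaf_order)

  ## newick export round-trips through ape with the same topology
  nwk <- cluster_newick(cl2)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, rownames(D))
})

test_that("unique_shared implements the >=2-samples-per-segment rule", {
  mkcalls <- function(df, tiles) {
    dt <- data.table::as.data.table(df)
    data.table::set(dt, j = "tiles", value = tiles)
    dt
  }
  ## one call in one sample only
  calls <- mkcalls(data.frame(sample = "s1", chrom = "1", start = 0, end = 1e5,
                              delta = -0.5, direction = "loss",
                              size_class = "focal", shared = NA),
                   list(1L))
  us <- unique_shared(calls)
  expect_equal(us$unique, 1L)
  expect_equal(us$shared, 0L)

  ## same segment lost in 2 of 4 samples: both occurrences shared
  calls <- mkcalls(data.frame(sample = c("s1", "s2", "s3"), chrom = "1",
                              start = 0, end = 1e5, delta = -0.5,
                              direction = c("loss", "loss", "gain"),
                              size_class = "focal", shared = NA),
                   list(1L, 1L, 2L))
  us <- unique_shared(calls, samples_in_scope = c("s1", "s2", "s3", "s4"))
  expect_equal(us$shared, 2L)  # the gain on another tile stays unique
  expect_equal(us$unique, 1L)
  expect_equal(us$unique + us$shared, nrow(calls))

  ## same tile altered in opposite directions is NOT shared
  calls <- mkcalls(data.frame(sample = c("s1", "s2"), chrom = "1", start = 0,
                              end = 1e5, delta = c(-0.5, 0.5),
                              direction = c("loss", "gain"),
                              size_class = "focal", shared = NA),
                   list(1L, 1L))
  us <- unique_shared(calls)
  expect_equal(us$shared, 0L)
  expect_equal(us$unique, 2L)
})

test_that("planted unique/shared events are recovered exactly at zero jitter", {
  d <- simulate_drift_experiment(seed = 3, jitter_sd = 0)
  rm_ <- reduce_segments(d$cohort)
  ctrl_ids <- names(d$groups)[d$groups == "ctrl"]
  bl <- baseline_mean(rm_, ctrl_ids)
  calls <- call_differential(rm_, bl)
  tr <- d$truth
  n_ctrl_sh <- nrow(unique(tr[tr$group == "ctrl" & tr$kind == "shared",
                              c("chrom", "start", "end")]))
  for (g in unique(d$groups)) {
    ids <- names(d$groups)[d$groups == g]
    us <- unique_shared(calls, samples_in_scope = ids)
    got <- us$calls[us$calls$sample %in% ids, ]
    planted_unique <- sum(tr$group == g & tr$kind == "unique")
    expect_equal(sum(!got$shared), planted_unique)
    if (g == "ctrl") {
      ## each control shared event: 2 carriers + 2 mirrored deviations
      expect_equal(sum(got$shared), 4L * n_ctrl_sh)
    } else {
      planted_shared_occ <- sum(tr$group == g & tr$kind == "shared")
      ## plus one mirror call per sample for every control shared event
      expect_equal(sum(got$shared),
                   planted_shared_occ + length(ids) * n_ctrl_sh)
    }
  }
})

test_that("fisher_randomness equals exhaustive hypergeometric enumeration", {
  ## independent oracle: enumerate all tables with the observed margins
  enum_fisher <- function(tab) {
    r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
    c1 <- sum(tab[, 1]); N <- sum(tab)
    p_of <- function(a) {
      b <- r1 - a; c_ <- c1 - a; d <- r2 - c_
      if (b < 0 || c_ < 0 || d < 0) return(NA_real_)
      choose(r1, a) * choose(r2, c_) / choose(N, c1)
    }
    probs <- vapply(0:min(r1, c1), p_of, numeric(1))
    probs <- probs[!is.na(probs)]
    p_obs <- p_of(tab[1, 1])
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  expect_equal(fisher_randomness(c(5, 5), c(5, 5))$p_value, 1)
  expect_equal(fisher_randomness(c(5, 5), c(5, 5))$odds_ratio, 1)

  ft <- fisher_randomness(c(10, 1), c(1, 10))
  expect_equal(ft$p_value, enum_fisher(rbind(c(10, 1), c(1, 10))))

  ## swapping the rows inverts the odds ratio, p unchanged
  ft2 <- fisher_randomness(c(1, 10), c(10, 1))
  expect_equal(ft2$odds_ratio, 1 / ft$odds_ratio)
  expect_equal(ft2$p_value, ft$p_value)

  ## random tables with margins <= 30 against the oracle and fisher.test
  set.seed(5)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 5), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    ft <- fisher_randomness(tab[1, ], tab[2, ])
    expect_equal(ft$p_value, enum_fisher(tab), tolerance = 1e-12)
    expect_equal(ft$p_value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }

  ## degenerate margin: p = 1 with a warning
  expect_warning(ft0 <- fisher_randomness(c(0, 5), c(0, 7)), "degenerate")
  expect_equal(ft0$p_value, 1)
})

test_that("drift_summary ties the pieces together", {
  d <- simulate_drift_experiment(seed = 17)
  rm_ <- reduce_segments(d$cohort)
  ctrl_ids <- names(d$groups)[d$groups == "ctrl"]
  calls <- call_differential(rm_, baseline_mean(rm_, ctrl_ids))
  dr <- drift_summary(rm_, calls, d$groups, control_ids = ctrl_ids)
  expect_setequal(dr$unique_shared$group, c("ctrl", "kd_a", "kd_b"))
  expect_equal(length(dr$fisher_tests), 3L)
  expect_true(all(vapply(dr$fisher_tests, function(f)
    f$p_value >= 0 && f$p_value <= 1, logical(1))))
  ## per-group tallies conserve total in-scope occurrences
  tot <- sum(dr$unique_shared$unique + dr$unique_shared$shared)
  expect_equal(tot, nrow(calls))
  ## cohort-wide scope also partitions the calls
  dr2 <- drift_summary(rm_, calls, d$groups, scope = "cohort")
  tot2 <- sum(dr2$unique_shared$unique + dr2$unique_shared$shared)
  expect_equal(tot2, nrow(calls))
})
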