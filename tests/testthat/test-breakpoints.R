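toy_calls <- function(df) {
  data.table::as.data.table(df)
}

test_that("classify_edges implements the window and track definitions", {
  ann <- toy_annotation()
  calls <- toy_calls(data.frame(
    sample = "s1", chrom = "1",
    start = c(1.5e6, 4.9e7, 2.05e7),
    end = c(5e6, 5.05e7, 2.5e7)))
  cls <- classify_edges(calls, ann)
  expect_equal(nrow(cls), 6L)
  e <- function(call, which) cls[cls$call_id == call & cls$edge == which, ]

  ## edge at 1.5 Mb on a 100 Mb chromosome: telomeric
  expect_true(e(1, "start")$telomeric)
  expect_false(e(1, "end")$telomeric)
  ## edge inside GENE2 [49 Mb, 51 Mb): intragenic with the gene listed
  expect_true(e(2, "start")$intragenic)
  expect_equal(e(2, "start")$genes_hit[[1]], "GENE2")
  ## centromere [45, 47] Mb +/- 2 Mb window: 49 Mb is NOT centromeric,
  ## 46 Mb-side start of call 2 is; fragile site [20, 21] Mb covers 20.5 Mb
  expect_false(e(2, "start")$centromeric)
  expect_true(e(3, "start")$fragile)
  expect_false(e(3, "end")$fragile)

  ## telomeric near the far end, and flags are non-exclusive
  far <- classify_edges(toy_calls(data.frame(sample = "s", chrom = "1",
                                             start = 9e7, end = 9.95e7)), ann)
  expect_true(far$telomeric[far$edge == "end"])

  ## unknown chromosome errors
  expect_error(classify_edges(toy_calls(data.frame(sample = "s", chrom = "7",
                                                   start = 0, end = 10)), ann),
               class = "segstack_validation_error")
})

test_that("classification equals brute-force membership on random edges", {
  ann <- toy_annotation()
  set.seed(31)
  n <- 250  # 500 edges
  calls <- toy_calls(data.frame(
    sample = "r", chrom = sample(c("1", "2"), n, replace = TRUE)))
  L <- ann$build$chrom_lengths[calls$chrom]
  calls$start <- floor(runif(n, 0, L - 1e6))
  calls$end <- calls$start + floor(runif(n, 1, 1e6))
  cls <- classify_edges(calls, ann)

  W <- ann$telomere_window_bp
  inside <- function(p, s, e) p >= s & p < e
  for (i in seq_len(nrow(cls))) {
    ch <- cls$chrom[i]; p <- cls$pos[i]
    Lc <- ann$build$chrom_lengths[[ch]]
    expect_equal(cls$telomeric[i], p < W || (Lc - p) < W)
    cen <- ann$centromeres[ann$centromeres$chrom == ch, ]
    expect_equal(cls$centromeric[i],
                 nrow(cen) > 0 && inside(p, cen$start - W, cen$end + W))
    g <- ann$genes[ann$genes$chrom == ch, ]
    hits <- g$gene_id[inside(p, g$start, g$end)]
    expect_equal(cls$intragenic[i], length(hits) > 0)
    expect_setequal(cls$genes_hit[[i]], hits)
    fr <- ann$fragile_sites[ann$fragile_sites$chrom == ch, ]
    expect_equal(cls$fragile[i],
                 nrow(fr) > 0 && any(inside(p, fr$start, fr$end)))
  }
})

test_that("genes_at_edges emits sizes and available expression only", {
  ann <- toy_annotation()
  calls <- toy_calls(data.frame(
    sample = "s", chrom = c("1", "1", "2"),
    start = c(200, 3e7, 1.1e7),     # in GENE1 (400 bp); intergenic; in BIGGENE
    end = c(1e6, 3.5e7, 1.3e7)))
  cls <- classify_edges(calls, ann)
  ge <- genes_at_edges(cls, ann)
  expect_setequal(ge$gene_ids, c("GENE1", "BIGGENE"))
  expect_setequal(ge$sizes, c(400, 2e6))
  ## GENE2 absent from the expression table contributes nothing;
  ## values for the two annotated genes come through
  expect_setequal(ge$expression, c(8.5, 2.1))

  ## an edge inside GENE2 adds a size but no expression value
  calls2 <- toy_calls(data.frame(sample = "s", chrom = "1",
                                 start = 5e7, end = 6e7))
  ge2 <- genes_at_edges(classify_edges(calls2, ann), ann)
  expect_equal(ge2$gene_ids, "GENE2")
  expect_equal(ge2$sizes, 2e6)
  expect_length(ge2$expression, 0L)
})

test_that("permutation null preserves chromosome and length, deterministically", {
  ann <- toy_annotation()
  set.seed(2)
  calls <- toy_calls(data.frame(
    sample = "s", chrom = rep(c("1", "2"), each = 5),
    start = floor(runif(10, 0, 5e7))))
  calls$end <- calls$start + floor(runif(10, 1e4, 2e7))
  null <- permute_isochromosomal(calls, ann, n = 50, seed = 9)
  pc <- null$permuted_calls
  expect_equal(nrow(pc), 50L * nrow(calls))
  expect_equal(pc$chrom, rep(calls$chrom, 50))
  expect_equal(pc$end - pc$start, rep(calls$end - calls$start, 50))
  L <- ann$build$chrom_lengths[pc$chrom]
  expect_true(all(pc$start >= 0 & pc$end <= L))

  ## identical seed => identical null; different seed differs
  null2 <- permute_isochromosomal(calls, ann, n = 50, seed = 9)
  expect_identical(null2$permuted_calls, null$permuted_calls)
  expect_identical(null2$counts, null$counts)
  null3 <- permute_isochromosomal(calls, ann, n = 50, seed = 10)
  expect_false(identical(null3$permuted_calls, null$permuted_calls))

  ## a call of length L on a chromosome of length L can only sit at 0
  ann1 <- genome_annotation(genome_build("one", c(q = 1e6)))
  forced <- permute_isochromosomal(
    toy_calls(data.frame(sample = "s", chrom = "q", start = 0, end = 1e6)),
    ann1, n = 20, seed = 1)
  expect_true(all(forced$permuted_calls$start == 0))
  ## and a longer call errors, naming the call
  expect_error(permute_isochromosomal(
    toy_calls(data.frame(sample = "s", chrom = "q", start = 0, end = 2e6)),
    ann1, n = 5, seed = 1), "q:0-2", class = "segstack_validation_error")
})

test_that("null intragenic fraction matches the analytic genic fraction", {
  ## genes tile 50% of one chromosome uniformly; under uniform placement
  ## the expected intragenic-edge fraction is the genic fraction
  L <- 1e8
  gb <- genome_build("u", c(c1 = L))
  genes <- data.frame(gene_id = sprintf("g%02d", 1:50),
                      chrom = "c1",
                      start = seq(0, L - 2e6, by = 2e6),
                      end = seq(0, L - 2e6, by = 2e6) + 1e6)
  ann <- genome_annotation(gb, genes = genes)
  calls <- data.frame(sample = "s", chrom = "c1",
                      start = seq(1e6, 9e7, length.out = 25))
  calls$start <- floor(calls$start)
  calls$end <- calls$start + 5e5
  n_perm <- 1000
  null <- permute_isochromosomal(data.table::as.data.table(calls), ann,
                                 n = n_perm, seed = 4)
  n_edges <- 2 * nrow(calls)
  frac <- null$counts[, "intragenic"] / n_edges
  p_hat <- mean(frac)
  se <- sqrt(0.5 * 0.5 / (n_perm * n_edges))
  expect_lt(abs(p_hat - 0.5), 3 * se + 0.01)
})

test_that("enrichment p-values follow the add-one empirical rule", {
  obs_calls <- toy_calls(data.frame(sample = "s", chrom = "1",
                                    start = 1e6, end = 3e6))
  ann <- toy_annotation()
  cls <- classify_edges(obs_calls, ann)

  fake_null <- function(counts_tel) {
    counts <- matrix(0L, nrow = length(counts_tel), ncol = 5,
                     dimnames = list(NULL, segstack:::EDGE_CATEGORIES))
    counts[, "telomeric"] <- counts_tel
    structure(list(n_permutations = length(counts_tel), seed = 0,
                   counts = counts, gene_sizes = list(), expression = list()),
              class = "permutation_null")
  }
  ## observed telomeric count is 1 (the 1 Mb edge)
  expect_equal(sum(cls$telomeric), 1L)

  ## observed above every null count -> p = 1/(n+1); below every -> p = 1
  enr <- enrichment(cls, fake_null(rep(0L, 10)))
  expect_equal(enr$p_value[enr$category == "telomeric"], 1 / 11)
  enr <- enrichment(cls, fake_null(rep(5L, 10)))
  expect_equal(enr$p_value[enr$category == "telomeric"], 1)

  ## observed equal to the null maximum with exactly one tie: p = 2/(n+1)
  enr <- enrichment(cls, fake_null(c(rep(0L, 9), 1L)))
  expect_equal(enr$p_value[enr$category == "telomeric"], 2 / 11)

  ## p is always within [1/(n+1), 1]
  expect_true(all(enr$p_value >= 1 / 11 & enr$p_value <= 1))

  ## per-Mb normalization present when the annotation is supplied
  enr2 <- enrichment(cls, fake_null(rep(0L, 10)), annotation = ann)
  expect_true(all(c("track_mb", "observed_per_mb") %in% names(enr2)))
  expect_equal(enr2$track_mb[enr2$category == "telomeric"],
               (4 * 2e6) / 1e6)
})

test_that("telomere-biased breakpoints are detected as enrichment", {
  ## one replicate here (fast); the 20-replicate power check lives in the
  ## acceptance suite
  gb <- sim_genome(n_chrom = 3)
  ann <- genome_annotation(gb)
  tw <- telomere_windows(ann)
  d <- simulate_drift_experiment(groups = c(ctrl = 4L, kd = 4L),
                                 genome = gb, bias_tracks = tw,
                                 bias_weight = 5, seed = 44, jitter_sd = 0)
  rm_ <- reduce_segments(d$cohort)
  calls <- call_differential(rm_, baseline_mean(rm_, paste0("ctrl_", 1:4)))
  kd_calls <- calls[calls$sample %in% paste0("kd_", 1:4), ]
  cls <- classify_edges(kd_calls, ann)
  null <- permute_isochromosomal(kd_calls, ann, n = 200, seed = 45)
  enr <- enrichment(cls, null)
  expect_lt(enr$p_value[enr$category == "telomeric"], 0.05)
})
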