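## Shared fixtures: everything is built in code at test time.

toy_build <- function() genome_build("toy", c(`1` = 1e8, `2` = 8e7))

seg_row <- function(sample, chrom, start, end, log2, n_markers = NA_integer_) {
  data.frame(sample = sample, chrom = chrom, start = start, end = end,
             log2 = log2, n_markers = n_markers)
}

toy_annotation <- function(build = toy_build()) {
  genome_annotation(
    build,
    genes = data.frame(
      gene_id = c("GENE1", "GENE2", "BIGGENE"),
      chrom = c("1", "1", "2"),
      start = c(100, 4.9e7, 1e7),
      end = c(500, 5.1e7, 1.2e7)),
    centromeres = data.frame(chrom = c("1", "2"),
                             start = c(4.5e7, 3.5e7), end = c(4.7e7, 3.7e7)),
    fragile_sites = data.frame(chrom = "1", start = 2e7, end = 2.1e7),
    stable_sites = data.frame(chrom = "2", start = 5e7, end = 5.2e7),
    expression = c(GENE1 = 8.5, BIGGENE = 2.1))
}

random_cohort <- function(n_samples = 5, n_segs = 20, build = toy_build(),
                          seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(n_samples), function(i) {
    ch <- sample(names(build$chrom_lengths), 1)
    L <- build$chrom_lengths[[ch]]
    b <- sort(sample.int(L - 1, n_segs + 1))
    data.frame(sample = sprintf("r%02d", i), chrom = ch,
               start = b[-length(b)], end = b[-1],
               log2 = round(stats::rnorm(n_segs, 0, 0.5), 3))
  })
  cohort(do.call(rbind, rows), build = build)
}

## independent quadratic oracle for interval-overlap queries
brute_overlapping <- function(segs, chrom, start, end) {
  hit <- logical(nrow(segs))
  for (i in seq_len(nrow(segs))) {
    hit[i] <- segs$chrom[i] == chrom &&
      max(segs$start[i], start) < min(segs$end[i], end)
  }
  segs[hit, ]
}
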