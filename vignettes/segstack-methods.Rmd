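---
title: "Methods: copy-number co-alteration, drift and breakpoint statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number co-alteration, drift and breakpoint statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segstack)
```

# The model and its assumptions

segstack works downstream of segmentation. Its unit of data is the
*segment*: a contiguous interval of one sample's genome carrying a log2
copy-number ratio, with 0 meaning reference ploidy. Everything the package
computes — co-alteration categories, differential calls, drift distances,
breakpoint enrichments — is a function of these segment tables plus
annotation tracks. The implicit assumptions are the usual ones for
segmented CNA data: segments of one sample do not overlap (segmenters emit
partitions; overlapping input is treated as corrupt unless the user opts
into marker-weighted merging), log2 values are comparable across samples
(i.e. profiles were normalized upstream), and a fixed threshold on |log2|
separates altered from neutral copy number.

Internally all coordinates are 0-based half-open, which makes overlap and
length arithmetic exact; SEG-style files are 1-based inclusive on disk and
converted on the way in and out (the conversion is self-inverse, asserted
by round-trip tests). Chromosome labels are canonicalized by stripping
`chr` prefixes.

# Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| loss / gain threshold | −0.2 / +0.2 | log2 ratio | the conventional "at least 0.2 units deviant" rule for calling a segment altered against a reference; roughly a 13% copy change, sensitive to monoallelic loss in impure material |
| telomere window | 2 Mb | bp | the common definition of a telomeric/centromeric break for tumor break-site analyses; applied to both chromosome ends and to both centromere flanks, since the centromere is an interval |
| focal / large size classes | < 100 kb / > 1 Mb | bp | the standard split between focal events (gene-scale lesions) and chromosome-arm-scale events; half-open so 100 kb exactly is intermediate |
| merge gap tolerance | 0 | bp | called tiles merge only when genomically adjacent; a missing or sub-threshold tile breaks the event, so event counts reflect discrete CNAs, not segmentation granularity |
| permutations | 1,000 | — | resolution of 1/1001 on empirical p-values at acceptable cost |
| linkage | average (UPGMA) | — | no linkage is canonical for CNA drift trees; average linkage is robust to the unequal cluster sizes typical of control-vs-perturbed designs. Samples are pre-sorted lexicographically so distance ties resolve deterministically |

# Co-alteration semantics

A segment *qualifies* for a region when it overlaps it by at least 1 bp
and passes the direction's threshold. No reciprocal-overlap fraction is
required: gene spans (first exon start to last exon end) are small
relative to typical deletions, and fraction rules would silently change
cohort counts. Coincidence is a *per-tumor* property by default — two
separate qualifying segments, or even segments on different chromosomes,
make a tumor coincident — because the scientific question ("is this tumor
deleted for both genes?") is about the tumor, not about lesion geometry.
A `single_segment` switch restricts coincidence to one segment spanning
both regions for users asking the lesion-geometry question; under that
semantics a tumor hit in both regions by separate segments is reported as
`exclusive_a` (region A takes precedence, documented and deterministic).

The stacked rendering orders bars losses-first, then by category, then by
start, and emits hand-built SVG so identical input yields byte-identical
output — a property the tests assert, and the reason no plotting library
sits in this path.

# Reduced segments and differential calling

Comparing segmentations across samples requires a common frame: the
*reduced-segment* tiling takes the union of all samples' breakpoints per
chromosome and keeps the tiles covered by at least one sample. Each
sample then has exactly one value per tile (or missing where uncovered),
and the reduction is idempotent. The "normal" reference is the unweighted
per-tile mean of the designated control samples; a tile missing in any
control is missing in the baseline rather than imputed. A tile is called
in a sample when its deviation from the baseline reaches the threshold,
and adjacent same-direction called tiles merge into one event whose delta
is the length-weighted mean.

A consequence worth stating explicitly, because it shapes both real
analyses and the synthetic tests: the control mean is *self-referential*.
An event of amplitude `a` present in `k` of `m` controls shifts the
baseline by `k·a/m`, so its carriers measure `a·(1 − k/m)` and every
non-carrier sample "mirrors" it at `−k·a/m`. Large control events
therefore echo across the whole cohort. This is not a bug of the
implementation but a property of the method; the drift generator (below)
is parameterized so these echoes are either silent or exactly
predictable.

# Drift statistics

Distances are plain Euclidean over the reduced-segment vectors,
pairwise-complete over missing tiles (with the per-pair tile count
attached so comparability can be judged), optionally after subtracting
the control baseline — a constant shift cancels in pairwise differences,
so both modes agree on shared tiles. Sharedness of a call means the same
reduced segment called in the same direction in ≥ 2 in-scope samples;
scope defaults to the comparison group, with a cohort-wide option, since
either reading of "found in at least two samples" is defensible. The
unique/shared ratio is compared between groups with a two-sided Fisher's
exact test implemented by the point-probability rule (sum of all
fixed-margin tables no more probable than the observed); the test suite
checks it against an independent exhaustive enumeration, and the reported
odds ratio is the sample odds ratio.

# Breakpoint enrichment

Both edges of every call are classified independently against five
non-exclusive flags (telomeric, centromeric, intragenic with genes
listed, fragile, stable). The null model relocates each call to a
uniform random start on its own chromosome, preserving chromosome and
exact length — an *iso-chromosomal* permutation, which controls for
per-chromosome event burden and length distribution while randomizing
position. Empirical p-values use the add-one rule
`(1 + #{null ≥ observed}) / (n + 1)`, bounded away from zero. Because no
normalization of per-category counts is canonical, both raw edge counts
and per-Mb-of-track rates are emitted. Random placements are not masked
against assembly gaps by default; users with a gap track can pre-filter
their annotation.

# What the synthetic generators emulate — and what they do not

`simulate_coalteration_cohort()` plants an exact category composition
over two query regions (default: two 100 kb genes 20 Mb apart on a
120 Mb chromosome), with half of the `none` samples carrying a decoy at
half the threshold so threshold logic is exercised.

`simulate_drift_experiment()` emulates a serial-passage design: a common
ancestral profile (whole-genome coverage plus three fixed ancestral CNAs,
so the reduction works on non-trivial input), groups of isolates (default
4 + 4 + 4, one control), Poisson numbers of private and group-shared de
novo events with log-uniform lengths on [10 kb, 10 Mb], amplitudes of
±[0.3, 1.0] log2 units, and per-segment Gaussian jitter (default
s.d. 0.02). All planted events are mutually disjoint and avoid the
ancestral CNAs, so the planted labels are recoverable. Because of the
baseline self-reference described above, control-group events are drawn
in a regime where the echo arithmetic is exact: control private
amplitudes are capped at 0.75 (carrier measures ≥ 0.225, mirrors stay
≤ 0.1875, below threshold), and control shared events go to exactly 2 of
4 controls with amplitudes in [0.45, 0.75] (all four controls deviate by
`a/2 ≥ 0.225`, so one planted event surfaces as 4 shared control calls
plus one mirror call in every non-control sample). The zero-jitter
acceptance test asserts this closed-form call table. Default rates
(perturbed: 12 private/sample, 2 shared/group; controls: 3 and 2) put the
expected unique/shared occurrence ratios near 1.5 for controls and 3.4
for perturbed groups — the contrast between spontaneous and
instability-driven drift this assay is used to detect. The
`shared_in_all` switch plants perturbed-group shared events in every
group member, the clonal/genotype-driven geometry needed for clean
two-group clustering; with random ≥ 2 carriers (the default) an event
carried by a strict subset separates group members as much as it
separates groups, and no clean dendrogram split should be expected.

`simulate_windowed_profile()` emulates normalized low-pass coverage:
500 kb windows, planted events as runs of 2–6 windows separated by at
least one neutral window, amplitudes ±[0.3, 1.0], window noise
s.d. 0.05, and a matched normal centered at zero.

Every generator draws one RNG stream per (seed, label) pair, so adding a
sample never perturbs another sample's data and fixed seeds reproduce
output byte for byte.

What the generators deliberately do **not** model: probe- or read-level
noise structure (segment means are drawn directly), GC/mappability waves,
subclonality and purity dilution, replication-timing or chromatin context
for breakpoints, and whole-arm aneuploidy geometry (event lengths are
log-uniform, not bimodal). A green test therefore establishes the
correctness of the interval arithmetic, calling rules, statistics and
reproducibility — not performance on noisy production arrays.

# Numerical choices and degenerate inputs

* Thresholds are inclusive (`|x| ≥ t`), matching "at least 0.2 units".
* Windows/tiles with missing values never qualify, never merge and are
  never imputed.
* A Fisher table with a zero margin returns p = 1 with a warning rather
  than an error, since downstream group sweeps may legitimately produce
  empty categories; an all-zero table is an error.
* The unique/shared ratio with zero shared calls is reported `NA`
  (undefined), not infinity.
* A permuted call exactly the length of its chromosome has one legal
  placement (start 0) and is handled; a longer call is an error naming
  the call.
* Segment files with `end < start`, non-numeric coordinates or unknown
  chromosomes fail with classed errors naming the line; nothing is
  silently dropped.

# Known limitations

* The TCGA dialect accepts a user-supplied column map rather than
  guessing release-specific headers.
* `fisher_randomness` enumerates the hypergeometric support directly;
  for the event-count scales of this domain (tens to hundreds) this is
  exact and fast, but it is not meant for tables with margins in the
  millions.
* The renderer draws one chromosome panel; cross-chromosome region pairs
  must be rendered per chromosome.
* Distances are not length-weighted: each reduced segment contributes
  equally, so many small tiles can outweigh one large one. This matches
  the reduced-segment convention but is worth remembering when cohorts
  differ strongly in breakpoint density.
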