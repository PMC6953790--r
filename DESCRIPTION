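Package: segstack
Title: Co-Alteration Queries, Differential Calling and Breakpoint
    Statistics for Segmented Somatic Copy-Number Profiles
Version: 0.1.0
Authors@R:
    person("Segstack", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for segmented somatic copy-number (SEG-style) cohorts:
    classify per-tumor co-deletion/co-amplification of gene pairs with
    stacked SVG rendering, build cross-sample reduced-segment matrices and
    call differential copy-number alterations against a control-mean
    baseline, quantify genetic drift (Euclidean distances, hierarchical
    clustering, unique-versus-shared event ratios with Fisher's exact
    comparison), classify CNA breakpoints against telomere, centromere,
    gene and fragile-site tracks with an iso-chromosomal permutation null,
    and count per-chromosome events in windowed low-pass profiles.
    Includes ground-truth synthetic cohort generators and a subcommand
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
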