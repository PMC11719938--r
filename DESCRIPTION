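Package: ppsieve
Title: Detecting Processed Pseudogenes and Sieving the Variant Artifacts They Cause
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects processed pseudogenes (intronless, reverse-transcribed gene
    copies) in short-read whole-genome cohorts from the intronic-deletion
    signature they leave in structural-variant calls, validates calls with the
    exon/intron coverage ratio and allelic-balance diagnostics, and flags
    clinically labelled small variants in the parent genes that are likely
    pseudogene-derived artifacts (junction-proximal, carrier-restricted under a
    chi-squared cohort association test, and allele-balance shifted). Includes a
    synthetic-cohort simulator that emits gene annotations, deletion VCFs, depth
    tracks and small-variant VCFs with a ground-truth table, so the whole
    pipeline is testable end to end, plus a command-line front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
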