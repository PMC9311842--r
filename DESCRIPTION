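Package: transdux
Title: Post-Processing and Population Genetics of Mobile Element 3'
    Transduction Call Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the downstream analysis of polymorphic mobile element
    insertion (MEI) call sets produced by split-read callers in a MELT-like
    VCF dialect, with a focus on LINE-1 and SVA 3' DNA transductions.
    Provides quality filtering of polymorphic insertions, two-tier
    classification of transduction candidates (segmental-duplication
    removal, read support, source/offspring length consistency, active
    subfamily membership), stratified allele frequencies and an exact
    Hardy-Weinberg test, population specificity and singleton summaries,
    progenitor-offspring mapping with prolific-source ranking,
    polyadenylation motif annotation (PAS, USE, DSE) of donor 3' ends, and
    a fully seeded synthetic cohort generator with planted ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
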