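Package: svaltiscan
Title: Structural-Variant Population Genetics for High-Altitude
    Adaptation Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Cohort-scale structural-variant (SV) population genetics for
    studies of local adaptation, built around long-read SV call sets.
    Provides nonredundant catalog construction from per-caller and
    per-sample call sets (breakpoint-distance consensus and merging),
    sharing-class and growth-curve summaries, region and transposable-
    element annotation, Weir-Cockerham FST and the di population-
    differentiation statistic with Z-test outlier calling, kernel-density
    SV-hotspot detection with a permutation null and random-relocation
    enrichment tests, and donor-introgression classification validated by
    neighbor-joining trees of flanking-SNP haplotypes.  A built-in
    Balding-Nichols cohort simulator with planted hotspots, differentiated
    SVs and introgressed SVs makes every stage testable without external
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
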