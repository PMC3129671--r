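Package: hzkit
Title: Detection and Quantification of Contiguous Homozygosity in Dense SNP Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects runs of contiguous homozygosity (homozygous segments) in
    dense diploid SNP genotype panels using a four-stage gap- and error-aware
    heuristic, and quantifies their population-level structure. Segments are
    scored with homozygosity probability scores, robust MAD-based autozygosity
    calls and founder-haplotype frequencies estimated from a phased panel.
    Locus-level extent of overlapping homozygosity is summarised through
    intersecting segment length matrices, percentile-extent matrices and the
    ext_AUC statistic, with smoothing-spline peak detection, outlier peak
    regions, candidate fixed-region calling, Weir-Cockerham theta annotation
    of population differentiation, and a permutation Cramer-von Mises test
    for comparing two groups' segment-length distributions. A seeded
    synthetic-data generator with planted truth supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
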