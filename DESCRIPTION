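Package: methdual
Title: Dual-Assay (MeDIP/MRE) Methylome Comparison of Tumor and Normal Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for comparing whole-genome DNA methylomes assayed
    jointly by methylated-DNA immunoprecipitation sequencing (MeDIP-seq) and
    methylation-sensitive restriction enzyme sequencing (MRE-seq). Provides
    windowed differential methylation testing that integrates both assays under
    a conditional-binomial model with copy-number-aware exposures, recurrence
    and type-preferred consensus calling across tumor samples, regulatory
    annotation of differentially methylated regions (CpG islands and shores,
    chromatin-state promoter/enhancer merging, transposable-element subfamily
    enrichment, developmental methylation patterns), chromosome-scale RPKM
    profiles, and independent validation in a probe-array beta-value cohort.
    Includes a seeded synthetic-data generator (toy genome, latent methylomes
    with planted differentially methylated regions, Poisson count tracks,
    chromatin-state tracks, and an array-like validation cohort) so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    limma,
    generics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
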