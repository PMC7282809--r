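Package: cohesr
Title: Spike-In Calibrated ChIP-Seq Occupancy and Competitive Fitness
    Analysis for Cohesion Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of sister-chromatid cohesion experiments
    in budding yeast. Implements spike-in calibrated ChIP-seq occupancy
    quantification (sequential two-genome read partitioning, occupancy-ratio
    scaling, zero-filled per-base pileups, centromere/CDEIII-anchored
    meta-profiles, and chromosome-median occupancy comparisons between
    conditions), flow-cytometry competitive-fitness estimation (genotype
    log-ratio regression over cumulative generations, fluorophore-control
    correction, Welch tests), and precocious sister-separation proportions
    from scored-cell tables. A synthetic-data generator produces every input
    with known ground truth so the full pipeline is testable without
    sequencing or cytometry data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    Rsamtools,
    rtracklayer,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
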