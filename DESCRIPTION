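Package: glmvc
Title: GLM-Based Filtration of False Positive Variant Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Platform-aware filtration of false positive SNV and indel calls
    from amplicon-based targeted sequencing. Extracts a panel of 23 variant-
    characterizing parameters from GATK-style VCF annotations, read pileups
    and the reference sequence; quantifies each parameter's Akaike-weight
    relative variable importance over an enumerated logistic-GLM model space;
    trains per-platform, per-variant-type logistic models by AIC forward
    selection; estimates a sensitivity-preserving probability threshold; and
    applies the trained filter to separate true from false positive calls.
    Includes a synthetic-data generator emulating platform-specific error
    structure (e.g. false positive indels concentrated at long homopolymers)
    and evaluation helpers for sensitivity/PPV benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    vcfR,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
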