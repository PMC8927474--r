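Package: svlite
Title: Structural Variant Calling from Low-Depth Long-Read Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects structural variations (>= 1 kbp, up to multi-megabase
    pathogenic events) from low-depth (~4x) noisy long-read whole-genome
    sequencing. Combines split-read candidate discovery, a read-depth
    likelihood-ratio detector against a reference panel of normal samples,
    an SV-aware dynamic-programming breakpoint refiner that leaves at most
    one SV-induced jump unpenalized, and realignment-based validation
    against alternative reference sequences. Emits VCF 4.2 with typed SV
    records (DEL, DUP, INV, BND) and includes a synthetic-data simulator
    and a type-aware benchmarking module with breakpoint-distance
    allowances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    generics,
    Rcpp,
    stats,
    utils,
    Biostrings,
    IRanges,
    Rsamtools,
    GenomicAlignments
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
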