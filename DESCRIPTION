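Package: barcodeval
Title: Evaluation of DNA Barcode Markers for Species Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate candidate DNA barcode markers for
    multi-marker plant datasets: marker variability statistics
    (polymorphic and parsimony-informative sites, nucleotide diversity,
    haplotype counts), uncorrected p-distances with pairwise deletion,
    intra- versus interspecific distance partitions and barcoding-gap
    summaries, the 'best close match' species-identification test with a
    95 percent intraspecific-distance threshold, neighbor-joining trees
    with nonparametric bootstrap support and species-specific cluster
    scoring, marker-combination supermatrices, and a seeded coalescent
    simulator of multi-species, multi-marker sequence data for testing
    every stage without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    phangorn,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
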