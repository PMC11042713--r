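Package: jaydiet
Title: Diet Metabarcoding and Cached-Versus-Fresh Classification for a
    Food-Caching Bird
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for dietary-DNA metabarcoding analysis of a food-caching
    corvid: amplicon read quality control (primer trimming, length and
    windowed-quality filters, exact dereplication, minimum-abundance
    filter), identity-filtered taxonomic assignment with barcode-gap-driven
    rank fallback (p-distance matrices, within- versus between-taxon gap
    tests), compilation and tallying of a multi-method diet-observation
    dataset, and a rule-based classifier that designates food items as
    likely cached, likely fresh, either possible, or unknown from
    natural-history traits and snow-depth records. Includes a synthetic
    data generator (reference libraries with controlled divergence,
    error-bearing reads with Phred qualities, dated observations with
    known cached/fresh ground truth, and snow series) so the whole chain
    is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
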