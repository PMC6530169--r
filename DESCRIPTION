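Package: taxonmatch
Title: Fuzzy Resolution of Plant Species Names and Species Mention Annotation
Version: 0.1.0
Authors@R: person("Maintainer", "Package", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Resolves (possibly misspelled) plant species name strings to
    accepted taxonomic names using character n-gram candidate retrieval
    followed by Smith-Waterman local-alignment rescoring with record-coverage
    and initial-character constraints, and annotates species-level mentions
    (binomial nomenclature) in free text. Includes a seeded synthetic
    generator for taxonomies, misspelled query benchmarks and planted-mention
    documents, plus precision/recall evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
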