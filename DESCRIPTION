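Package: hftc
Title: Hierarchical Fungal Taxonomy Classification from ITS Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assigns fungal taxonomy to internal transcribed spacer (ITS)
    amplicon sequences with a hierarchy of random-forest sub-classifiers.
    Sequences are tokenized into k-mers from both orientations, embedded
    with skip-gram (word2vec) trained on the k-mer corpus, and pooled into
    compact fixed-length vectors. A recursively constructed classifier tree
    routes queries from phylum down to family and assigns species directly,
    guaranteeing taxonomically consistent lineages. Includes UNITE-style
    dataset curation (ambiguous-label and non-standard-base removal,
    species-hypothesis size filtering and subsampling), rank-wise and
    hierarchical accuracy metrics, and a taxonomy-aware ITS sequence
    simulator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    graphics,
    jsonlite,
    ranger,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
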