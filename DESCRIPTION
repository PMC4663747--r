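Package: microrep
Title: Linking Metabolic Repertoire, Phenotype, and Phylogeny in Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating the metabolic reaction repertoire of microbial
    genome-scale models to predicted phenotypes and phylogeny. Provides a
    compact JSON schema for constraint-based metabolic models, flux balance
    analysis with a rich-medium single-nutrient-removal essentiality screen,
    Jaccard distances on binary reaction and nutrient profiles, cophenetic
    (patristic) distances on rooted trees, principal coordinate analysis with
    discriminative-reaction loadings, t-SNE embeddings, complete-linkage
    sub-type clustering with differential reaction sets, exponential and
    linear cross-distance regressions, and a synthetic community generator
    with construction-time ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ape,
    Rtsne,
    yaml,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
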