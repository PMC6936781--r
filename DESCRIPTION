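Package: fermcore
Title: Functional Core Microbiota Screening from Paired Microbiome and
    Flavor Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of paired genus-level microbiome and
    flavor-component tables from food fermentations: alpha-diversity
    estimators and rarefaction, Hellinger/Bray-Curtis ordination with
    principal coordinates analysis and hierarchical clustering, a
    permutation multivariate ANOVA (PERMANOVA) with automatic exhaustive
    enumeration, flavor-block principal component analysis with
    cross-validated component significance, a bidirectional orthogonal
    partial least squares (O2PLS) cross-block latent model with variable
    importance in projection restricted to predictive components
    (VIP(pred)), thresholded genus-flavor correlation networks, and a
    three-criterion screen for the functional core microbiota. Includes a
    synthetic-data generator with planted joint latent structure and a
    planted core-taxon set so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    xml2
Config/testthat/edition: 3
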