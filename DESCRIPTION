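Package: stockdiscrim
Title: Fish Stock Identification from Morphometric and Fatty Acid Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for identifying fish stocks from morphological
    characters and heart-tissue fatty acid signatures. Provides allometric
    size adjustment of morphometric characters using common within-group
    slopes, outlier screening, two-way MANOVA and PERMANOVA screening of
    group and sex effects, stepwise multiple discriminant analysis with
    the Mahalanobis D-squared selection rule, leave-one-out cross-validated
    classification with Press's Q, discriminant loadings and potency
    indices, compositional fatty acid profile summaries (class and omega
    series sums, unsaturation index), and a seeded synthetic-data
    generator emulating the sampling design of a three-group sea lamprey
    stock study so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    vegan,
    car,
    yaml
Config/testthat/edition: 3
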