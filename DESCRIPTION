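Package: eabgauth
Title: Species Authentication of Edible Animal Blood Gel by Multi-Element Fingerprinting
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Chemometric pipeline for authenticating the animal species of
    edible blood gel ("blood tofu") from its 25-element concentration profile.
    Provides packaged reference class summaries (per-species means and
    standard deviations of absolute and relative element content for duck,
    chicken, bovine, pig and sheep), a moment-matched synthetic profile
    generator, Z-score and relative-content preprocessing, element selection
    by one-way ANOVA screening or stepwise discriminant analysis (Wilks'
    lambda), dimension reduction by PCA or Fisher linear discriminant
    analysis, Kennard-Stone sample set partitioning, an extreme learning
    machine classifier with sigmoid, sine and hard-limit activations, and an
    experiment driver that evaluates all 24 pipeline configurations over
    repeated fits with compact-letter significance displays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
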