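Package: speckleid
Title: Speckle-Pattern Texture Classification of Turbid Suspension Drugs
Version: 0.1.0
Authors@R:
    person("speckleid", "maintainers", email = "speckleid@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for identifying turbid pharmaceutical
    suspensions (parenteral nutrition admixtures) from laser speckle
    pattern images. Provides a physics-based dynamic speckle simulator
    parameterized by lipid concentration and refractive-index contrast,
    center-cropping and per-drug intensity normalization, a 129-feature
    texture descriptor (first-order statistics plus gray-level
    co-occurrence and run-length matrix statistics along four
    directions), local-outlier-factor sample filtering, Pearson
    collinearity pruning, grid-searched cross-validated Random Forest
    and Multi-Layer Perceptron classifiers, Shapley-value model
    explanation, and gray-level distribution statistics (one-way ANOVA
    and Tukey HSD).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    png,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
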