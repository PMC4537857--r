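Package: rootdiallel
Title: Root System Architecture Phenotyping and Diallel Analysis of Root
    Complexity Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Image-based phenotyping of washed root cores and quantitative
    genetics of the resulting traits. Binarized root silhouettes are reduced
    to four plot-level traits: box-counting fractal dimension (FD), fractal
    abundance (FA, the log intercept of the box-count power law), root cone
    angle (RA), and stalk diameter (SD). Plot means are analysed with a
    fixed-effects generation-block diallel model that separates additive
    line effects per se, general and specific combining ability, mid-parent
    heterosis, and check contrasts, with Type III tests and adaptive false
    discovery rate control. Correlation, principal component and clustering
    summaries describe the multivariate trait structure. A synthetic-data
    module generates fractal fixtures of known dimension, stochastic
    branching root systems, and diallel phenotype tables with known genetic
    effects, so every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
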