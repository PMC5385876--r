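Package: spectreff
Title: Spectrum-Effect Relationship Modelling for Herbal Formula Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links chromatographic fingerprint peak areas of formulation
    variants to multi-index pharmacology panels. Builds two-factor uniform
    designs by the good-lattice-point method scored with the centered L2
    discrepancy, reduces intercorrelated hemorheology and coagulation indices
    to varimax-rotated bioactivity factors, and ranks chemical components by
    grey relational analysis, gated stepwise regression, and radial basis
    function network permutation importance. The three rankings are aggregated
    into a consensus core-bioactive-component report and a bioactive
    fingerprint designation. A synthetic-study generator with planted
    component-effect structure supports parameter-recovery testing of every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
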