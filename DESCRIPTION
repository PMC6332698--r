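Package: prionscore
Title: Mutation Impact Scoring for Prion-Like Protein Aggregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the effect of amino-acid substitutions on the aggregation
    propensity of proteins bearing prion-like domains (PrLDs). Combines a
    disorder-gated, composition-based prion propensity profile (sliding-window
    averaging of a Sup35-derived per-residue scale, gated by a FoldIndex-style
    disorder track) with an amyloid-core score (best 21-residue stretch under a
    hexapeptide position-specific scoring matrix) into a single calibrated
    linear score, classifies variants against low/high thresholds, and supports
    reference-versus-variants comparison, single-position saturation scanning,
    predictor evaluation metrics, and synthetic PrLD simulation for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
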