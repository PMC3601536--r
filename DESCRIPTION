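Package: netintegr
Title: Measuring Service Integration in Inter-Agency Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies how well an inter-agency service network is
    integrated from paired perceived and expected involvement ratings on a
    5-point ordinal scale. Each agency receives four agreement scores
    (group-perceived vs group-expected, self-perceived vs group-expected,
    group-perceived vs self-expected, and self-perceived vs self-expected),
    and the network receives a global integration score estimated by the
    plain mean, an inverse-variance-weighted mean, and standard, balanced,
    and Bayesian bootstrap procedures with bias-corrected and accelerated
    (BCa) or credibility intervals. Includes a synthetic-network generator
    with analytic expected scores for validation, spider and
    integration-area plots, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    ggplot2,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
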