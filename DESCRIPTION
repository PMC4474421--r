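Package: cypnet
Title: Signed Compound-Regulator-CYP Interaction Networks and qPCR
    Validation Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds signed, directed compound-to-regulator-to-enzyme
    interaction networks from curated edge lists, applies degree and orphan
    filtering, merges layer networks, ranks regulator hub clusters, and
    traces sign-composed simple paths from compounds to terminal leaves to
    predict the direction of a compound's effect on cytochrome P450 (CYP)
    enzymes. Also provides the companion wet-lab validation statistics for
    dose-response qPCR experiments (relative fold change, one-way ANOVA via
    the F distribution, Tukey HSD via the studentized range distribution)
    and synthetic-data generators with full ground truth for both the
    curated-interaction database and the qPCR measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    pracma,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
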