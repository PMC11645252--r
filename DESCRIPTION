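Package: qmimic
Title: Matched-Pair Analysis of Food-Choice Mimicry in Checkout Queues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying purchasing mimicry between adjacent customers
    in point-of-sale queues. Extracts partner-focal dyads from timestamped
    transaction logs, builds matched pairs of treated and control dyads that
    agree on partner identity, shop, meal period, item availability and item
    popularity (within a caliper), and estimates paired risk differences and
    risk ratios with bootstrap confidence intervals. Includes the paired
    chi-squared test, subgroup estimation, a randomized-partner baseline,
    lag-binned dose-response regression, Rosenbaum sensitivity bounds with
    amplification, and a synthetic purchase-log generator with known
    ground-truth mimicry for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
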