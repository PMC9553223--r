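Package: memdisc
Title: Membership Disclosure Risk Assessment for Synthetic Tabular Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating and validating the membership disclosure
    risk of synthetic tabular health data. Implements Hamming-distance record
    matching against a synthetic table, the partitioning attack estimator with
    its corrected attack-set composition t = n/N, the F1/Fmax/M metric family
    with the M <= 0.2 acceptability rule, a risk-utility loss for generative
    model tuning, a sequential tree-based (CART) synthesizer and simple
    baselines, a synthetic-population generator for validation, and a
    simulation harness that compares the partitioning estimator against a
    ground-truth adversary attack.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rpart,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
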