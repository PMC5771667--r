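Package: dupsel
Title: Adaptive Value and Early Fate of Gene Duplication Under Expression Noise
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative framework for the intrinsic adaptive value of gene
    duplication in a noisy, regulated metabolic system, built around the lac
    operon of Escherichia coli. Provides the cost-benefit growth-rate model of
    lactose utilisation, deterministic and stochastic LacZ expression for
    singleton and duplicated genes under intrinsic and extrinsic log-normal
    noise, Monte-Carlo selection-coefficient distributions and landscapes,
    mutual-information analysis of the lactose-to-expression channel with a
    Fisher r-to-z significance test, synthetic generators for fluctuating
    lactose environments and promoter-mutant activity distributions, an
    agent-based serial-dilution evolution simulator, and closed-form
    population genetics of duplication formation, deletion and fixation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
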