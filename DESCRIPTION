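Package: gseqrand
Title: Randomization-Aware Operating Characteristics for Group
    Sequential Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how restricted randomization procedures
    interact with group sequential clinical trial designs in small
    samples.  Generates randomization sequences from seven restricted
    randomization procedures (complete randomization, random allocation
    rule, permuted blocks, Efron's biased coin, big stick, Chen's design
    and randomized blocks), computes efficacy and futility boundaries for
    classic Pocock and O'Brien-Fleming designs, Lan-DeMets alpha-spending
    designs and the inverse normal combination test, and evaluates exact
    (multivariate normal) and Monte Carlo type I error and power
    conditional on the stage-wise treatment allocations actually realised
    by a randomization sequence.  Includes quantile-substitution t-test
    boundaries, binding and non-binding futility, and a configuration
    driven experiment runner that reproduces the operating-characteristic
    tables of the underlying simulation study at configurable scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    mvtnorm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
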