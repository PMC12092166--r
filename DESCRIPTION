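Package: acsrci
Title: Compatibility Intervals for Active Comparator Sequence Ratios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Interval estimators for the active comparator sequence ratio
    used in sequence symmetry analysis: the Miettinen-Nurminen score
    interval, the Baptista-Pike mid-p interval, the Woolf logit interval,
    and variance-summation Wald intervals built on Clopper-Pearson,
    Jeffreys, or Agresti-Coull binomial proportion intervals. Includes a
    binomial simulation engine with a memoized scenario runner, exact
    (non-Monte-Carlo) coverage calculators that enumerate the bivariate
    binomial sample space, brute-force grid-inversion oracles for the
    test-inversion intervals, and coverage/divergence/Monte-Carlo-standard-
    error summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    ggplot2,
    yaml
Config/testthat/edition: 3
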