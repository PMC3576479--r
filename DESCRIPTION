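Package: permadapt
Title: Permutation Tests for Unplanned Blinded Adaptations in Randomized Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact and Monte-Carlo permutation (randomization) tests for two-arm
    trials, including stratified tests that condition on the per-arm sample sizes
    known at the time of an unplanned, pre-unblinding adaptation. Provides a
    blinded-view contract for adaptation rules operating on lumped (pooled,
    label-free) data, a catalog of legitimate and deliberately adversarial rules,
    exact conditional type I error computations for partially observed binary
    designs, and a Monte-Carlo simulation laboratory measuring rejection rates of
    fixed and adaptive analyses under strong and weak null hypotheses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
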