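Package: distractlearn
Title: Statistical Learning Models of Distractor Suppression in Visual Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how observers learn to suppress salient
    distractors that appear predictably at one spatial location in the
    additional-singleton visual search paradigm. Generates trial sequences
    with the paradigm's probability structure (50% distractor-present
    trials, a 66.67% high-probability distractor location, per-block target
    counterbalancing, constant or periodically changing schedules),
    implements nine candidate trial-level reaction-time models (frequency
    accumulator, Rescorla-Wagner prediction-error learning, and categorical
    all-or-nothing suppression, with block-reset and no-global-decay
    variants, plus a priming-only model), fits and compares them with a
    hierarchical Bayesian random-effects procedure (regularized per-subject
    MAP estimates, Laplace model evidence, responsibilities, exceedance and
    protected exceedance probabilities, Bayesian omnibus risk, hierarchical
    t-tests), and runs end-to-end model- and parameter-recovery simulations
    on fully synthetic data together with the paradigm's standard
    descriptive behavioral summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
LinkingTo:
    Rcpp
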