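Package: markov5csrtt
Title: Trial-by-Trial Markov Chain Diagnostics for Five-Choice Serial
    Reaction Time Task Sessions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates first-order discrete-time Markov chains and
    zeroth-order (independence) models from trial-outcome sequences of the
    five-choice serial reaction time task (5CSRTT), and tests whether trial
    outcomes depend on the immediately preceding trial. Provides the
    likelihood-ratio W (G) statistic over the full transition table, a
    restricted chi-squared test on transitions into a target state (by
    default premature responses), standardized (O - E)/sqrt(E) deviation
    profiles, and split-half homogeneity checks. Includes a synthetic
    session generator that reproduces the task's outcome taxonomy and
    blockwise pseudo-randomised partial-reinforcement schedules, macro-level
    session summaries with quartile-based impulsivity screening, and a
    reproducible generate-estimate-diagnose pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
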