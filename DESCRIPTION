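Package: fillitup
Title: Two-Stage Fill-it-up Designs with Historical Controls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Planning and analysis of two-arm superiority trials with a normal
    endpoint that borrow historical controls through a two-stage "fill it up"
    procedure: an equivalence pre-test on the randomized versus historical
    control means decides whether the historical controls are pooled into the
    control arm (stage-1 superiority test) or randomization is extended to the
    full sample size (stage-2 superiority test). Provides closed-form sample
    size allocation between the stages, admissible equivalence-margin bounds,
    the three z-test statistics and the combined decision rule, family-wise
    error rate and overall power by exact integration, by the linearized
    normal approximation of the pre-test, and by Monte-Carlo simulation, a
    patient-level trial-data format with generator and step-wise analysis
    workflow, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
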