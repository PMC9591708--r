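Package: thermoclean
Title: Artifact Reduction and Agreement Evaluation for Intraoperative Temperature Traces
Version: 0.1.0
Authors@R:
    person("MPOG", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements two artifact-reduction algorithms for automated
    intraoperative core-temperature recordings (a slope-based filter over
    three-point linear fits and an interval-based filter keyed on recording
    gaps), together with the evaluation machinery needed to validate such
    filters against expert adjudication: hypothermia area-under-curve burden,
    per-case summaries, majority-rule consensus, sensitivity/specificity and
    F-scores, Gwet's AC1 chance-corrected agreement with its variance
    estimator, Bland-Altman limits of agreement, leave-one-out jackknife
    diagnostics, and Bland-Altman agreement-study sample-size planning after
    Lu et al. A seeded generator of anesthesia-typical temperature traces
    with labeled injected artifacts makes the whole pipeline testable without
    patient data. A command-line entry point orchestrates
    simulate/filter/summarize/evaluate/samplesize runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
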