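Package: ppcmismatch
Title: Trial-Based Analysis of Calcium Imaging Mismatch Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trial-aligned analysis of two-photon calcium imaging recordings
    from auditory-tactile stimulus-sequence experiments. Provides per-trial
    dF/F normalization, shuffle-null (randomly placed same-session window)
    responsiveness classification with odd/even cross-validated selection,
    per-trial response probabilities, baseline-corrected population averages,
    pre-stimulus expectation metrics and mismatch/omission response
    quantification, together with a synthetic GECI-transient generator that
    plants category-specific responders with full ground truth for end-to-end
    verification of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'recording-methods.R'
    'trialtable-methods.R'
    'io.R'
    'simulate.R'
    'preprocess.R'
    'stat-tests.R'
    'responsiveness.R'
    'metrics.R'
    'pipeline.R'
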