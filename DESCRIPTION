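Package: glycotype
Title: Reverse ABO Blood Typing from Glycan Microarray Serum Antibody Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines ABO blood type from serum anti-glycan antibody profiles
    measured on glycan microarrays (reverse typing). Implements banded-threshold
    classifiers over log2 relative-fluorescence signals (two-component pairs,
    all-agree multi-component panels, and a two-stage 10-component flow chart),
    systematic threshold optimization under a classification-rate constraint,
    ANOVA-based ranking of array components by association with blood type, and
    mislabel-suspect flagging. Includes first-principles Kaplan-Meier estimation,
    log-rank testing, odds ratios, and survival-relative-to-prognosis analyses
    for typed patient cohorts, plus a synthetic serum-profile and cohort
    generator for end-to-end testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
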