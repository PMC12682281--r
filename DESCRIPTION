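Package: scalegeom
Title: Scale Geometry and Perceptual Sensitivity to Melodic Deviants
Version: 0.1.0
Authors@R: person("Scalegeom", "Developers", email = "scalegeom@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how the geometric structure of musical scales
    (evenness and interval-class content) relates to perceptual sensitivity to
    out-of-scale notes in melodies. Implements pitch-class set algebra in
    generalized equal-division tuning systems (enumeration of transpositional
    set classes, interval-class vectors, evenness scores), constrained
    random-walk melody generation with note-deviant and contour-deviant test
    melodies, a synthetic-participant simulator for two-alternative
    forced-choice responses, and the statistical pipeline: exclusion rules,
    the note/contour response-bias statistic, group tests, evenness
    correlation, and interval-vector ridge regression with permutation
    inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
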