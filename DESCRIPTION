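Package: hamscore
Title: Cohen MRI Scoring and Return-to-Sport Analysis for Acute Hamstring Injury
Version: 0.1.0
Authors@R: person("Aspen", "Reid", email = "aspen.reid@example.org", role = c("aut", "cre"))
Description: Implements the additive Cohen MRI severity score for acute
    hamstring muscle injury: a declarative, swappable rubric that converts a
    radiologist's structured MRI readings (muscles involved, injury location,
    insertional involvement, transverse cross-sectional percentage, tendon
    retraction, craniocaudal sagittal extent) plus athlete age into per-variable
    points and a total score. Provides exhaustive enumeration of the score's
    structural bounds, cohort description (category frequencies and continuous
    summaries), the standard prognostic evaluation of the score against
    return-to-sport duration (Pearson and tie-corrected Spearman correlation,
    variance explained, Lilliefors-corrected Kolmogorov-Smirnov normality,
    dichotomized group comparison with Welch confidence intervals and Cohen's d),
    and a seeded synthetic-cohort generator whose marginal category frequencies
    and moment-calibrated linear return-to-sport model emulate a cohort of 110
    MRI-positive injuries in professional footballers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
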