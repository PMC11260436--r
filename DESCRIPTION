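Package: tapkin
Title: Video-Derived Finger-Tapping Kinematics and Bradykinesia Severity Staging
Version: 0.1.0
Authors@R:
    person("tapkin", "developers", email = "tapkin@example.org", role = c("aut", "cre"))
Description: Quantifies bradykinesia from hand-landmark time series recorded
    during the MDS-UPDRS Finger Tapping test. Converts 21-point hand-pose
    landmark streams into a thumb-index angular displacement signal, applies
    zero-phase low-pass filtering, segments tapping cycles from signal peaks
    and valleys, and computes 13 kinematic features (amplitude, speed,
    opening/closing speed, cycle-duration statistics, tapping rate, and
    amplitude decay). Severity staging is performed with a tiered cascade of
    binary logistic models (control vs patient, score 1 vs 2-3, score 2 vs 3)
    and compared against multiclass and cumulative ordinal-binary baselines,
    with z-score normalization, SMOTE class balancing, recursive feature
    elimination, and precision-recall-based evaluation. Includes group
    statistics (Kolmogorov-Smirnov normality screening, ANOVA or Welch ANOVA,
    Tukey HSD with Bonferroni correction), a synthetic tapping-signal and
    cohort generator for end-to-end testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
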