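Package: figground
Title: Figure-Ground Analysis of Superior Colliculus Electrophysiology and Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for visual figure-detection experiments in head-fixed
    mice: psychometric analysis of accuracy versus optogenetic silencing onset with
    bootstrapped inflection points, envelope multi-unit activity (eMUA) artifact
    rejection, eye-movement trial exclusion, current-source-density depth assignment,
    sparse-noise receptive-field estimation with a bootstrapped variability index,
    figure-ground modulation statistics based on cluster permutation tests with
    mixed-model statistics and latency fits, pseudo-population decoding with a
    balanced bootstrap linear support vector machine, and d-prime discriminability
    including hit versus error comparisons. Includes synthetic-session generators
    with known ground truth for parameter-recovery and type-I-error testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    signal,
    minpack.lm,
    e1071,
    lme4,
    lmerTest,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
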