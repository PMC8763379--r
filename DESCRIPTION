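Package: sonomyo
Title: Sonomyography Gesture Classification and Feature-Space Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing sonomyography (ultrasound-based muscle
    sensing) gesture data: a synthetic speckle-image generator emulating
    cued motion protocols, cue-aligned frame extraction and dataset IO, a
    class-averaged Pearson-correlation nearest-class classifier with
    leave-one-out cross-validation, PCA projection of pixel vectors with
    Mahalanobis cluster consistency/separability metrics (within-class
    distance, inter-class nearest/all-neighbor distances, most separable
    dimension, mean semi-principal axis), a real-time style biofeedback
    correlation trace, and permutation-tested linear mixed models with
    subject random intercepts for longitudinal outcome analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    png,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
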