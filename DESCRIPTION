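Package: orthoretract
Title: Kinematics and Tissue Resistance of Orthodontic Canine Retraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of orthodontic distal canine retraction from sparse
    clinical measurements. From per-cycle crown-tip and apex displacements and
    tooth geometry it estimates the center of rotation along the tooth long
    axis, classifies the movement (rotation, roto-translation, translation),
    computes a weighting coefficient of the summed periodontal-ligament and
    alveolar-bone resistance from the applied elastomeric-chain force, and
    calibrates the coefficient's polynomial denominator weights from observed
    values by non-negative least squares. Includes exponential and piecewise
    force-decay models for elastomeric chains, a synthetic-cohort generator
    with known ground truth for validating every pipeline stage, cohort
    readers/writers (CSV/JSON), and an end-to-end analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    MASS,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
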