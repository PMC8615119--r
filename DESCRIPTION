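Package: ataamech
Title: Patient-Specific Biomechanics of the Ascending Thoracic Aortic Aneurysm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully testable implementation of a patient-specific
    computational chain for ascending thoracic aortic aneurysm (ATAA)
    biomechanics: anisotropic hyperelastic (Holzapfel-Ogden)
    material-parameter estimation from planar equibiaxial test data, a
    clinically calibrated time-varying-elastance plus three-element
    Windkessel circulation with pressure-volume-loop metrics, an analytic
    surrogate for aortic wall stress under luminal pressure, ventricular
    traction and arc bending, and three-section eight-quadrant
    inner/outer-surface stress summaries. A seeded synthetic-data module
    generates every input the pipeline needs, so the whole chain runs and is
    verified without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    deSolve,
    minpack.lm,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
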