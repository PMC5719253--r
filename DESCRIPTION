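Package: fibroquant
Title: Quantitative Imaging and Micromechanics of Fibrillar Collagen Remodelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantifying fibrillar collagen remodelling
    and tissue mechanics in lung fibrosis. Computes forward/backward
    second-harmonic-generation (SHG) collagen maturity metrics from
    two-channel image stacks, quantifies DAB immunohistochemistry by
    optical-density colour deconvolution, estimates Young's modulus from
    sphere-tipped AFM micro-indentation force curves via the Hertz contact
    model, and integrates per-subject measurements with normality-gated group
    tests, correlations and principal-axis factor analysis with promax
    rotation. Ships synthetic-data generators (SHG stacks, brightfield IHC
    images, force curves, latent-factor cohorts) with known ground truth so
    every stage is testable without tissue images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    tiff,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
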