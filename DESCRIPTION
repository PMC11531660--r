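Package: elbowaxes
Title: Rotational and Translational Deviation Between the Elbow's Epicondylar and Flexion-Extension Axes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-dimensional morphometric analysis of distal-humerus surface
    models. Fits the long (intramedullary) axis from elliptical shaft
    cross-sections, the true flexion-extension axis from a Gauss-Newton circle
    fit to trochlear-groove landmarks, and the epicondylar axis from averaged
    epicondyle picks; builds the anatomical coronal/sagittal/axial frame and
    quantifies the per-plane rotational differences and the per-direction
    translational offsets between the epicondylar and flexion-extension axes.
    Includes a parametric synthetic-specimen generator with exact ground truth
    for parameter-recovery validation, and cohort statistics (normality,
    Student's t-tests, two-way intraclass correlation coefficients).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
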