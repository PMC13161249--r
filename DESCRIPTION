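Package: ildsel
Title: Resampling-Based Selection of Group-Dimorphic Interlandmark
    Distances and Contour-Plot Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for traditional morphometric analysis of interlandmark
    distances (ILDs) computed from 2D/3D anatomical landmark
    configurations. Provides generalized Procrustes superimposition
    without scaling (form space), object-symmetry symmetrization,
    enumeration and structural de-duplication of all pairwise ILDs,
    bootstrap-supported selection of the ILDs most strongly associated
    with a two-group factor (such as sex) or a covariate, a randomized
    balanced-subsampling robustness experiment, two-group linear
    discriminant analysis with leave-one-out cross-validation and
    typicality probabilities, and thin-plate-spline posterior-probability
    contour plots that classify new cases graphically in a two-ILD data
    space. A synthetic-data module generates bilaterally symmetric
    landmark datasets with planted dimorphism for validation and power
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    mgcv
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
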