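Package: cardioeik
Title: Rule-Based Anisotropic Eikonal Models of Ventricular Activation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the electrical activation of the ventricles with an
    anisotropic eikonal model on labeled tetrahedral meshes. Provides
    rule-based myofiber orientation, six conduction-substrate variants
    (normal, scar, anterior/posterior functional block, slow septal
    conduction, fast endocardial conduction), calibration of the bulk
    conduction velocity to a measured QRS duration, and validation metrics
    (temporal and isochrone distance errors) against electro-anatomical
    mapping points. Includes synthetic slab and biventricular geometries and
    a synthetic mapping-data generator so the full study pipeline runs
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
SystemRequirements: C++17
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
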