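Package: epidverify
Title: In Vivo EPID Transit Dosimetry Verification with a Learned Detector Response
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for two-dimensional in vivo treatment verification of static-gantry
    IMRT fields with an electronic portal imaging device (EPID). The package splits a
    DICOM RT plan into single-field zero-gantry plans, builds the "combined CT" (couch
    substitution, axial counter-rotation by the gantry angle, axial extension, and
    insertion of a 5 cm solid-water slab standing in for the EPID), extracts and
    resamples the equivalent-EPID dose plane, trains a U-net that converts Monte-Carlo
    style water-dose maps into EPID transmission images, and compares predicted against
    measured transmission images with a 2D global gamma analysis including a
    delivery-error sensitivity protocol. A parametric detector-response simulator
    (attenuation, off-axis response, glare, MC-like noise) generates paired training
    data so the whole pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite, yaml, Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, png, tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
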