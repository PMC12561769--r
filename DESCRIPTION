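Package: protorange
Title: Protoacoustic Proton Range Verification in Heterogeneous Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation pipeline for time-of-flight proton range verification
    from protoacoustic (ionoacoustic) pressure waves. Builds voxel phantoms
    with CT-number- or temperature-derived acoustic properties (thermal water,
    homogeneous and bimaterial tissue phantoms, CT-like labelled volumes),
    models the thermoacoustic source generated at the proton Bragg peak
    (Grueneisen-scaled initial pressure with a Gaussian temporal pulse),
    propagates pressure waves through heterogeneous media with a staggered-grid
    finite-difference solver (8th-order stencils, perfectly matched layers,
    power-law acoustic absorption), and estimates the Bragg-peak-to-detector
    distance from the detected arrival time and the path-averaged speed of
    sound, quantifying the range error induced by material heterogeneity.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
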