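Package: dgnrange
Title: Patient-Specific Normalized Glandular Dose Ranges for Mammography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the range of normalized glandular dose (DgN) consistent
    with a single mammographic projection and its per-pixel glandular-fraction
    map. Builds voxelized compressed-breast phantoms (adipose, fibroglandular,
    skin), models a filtered tungsten-anode spectrum, forward-projects
    phantoms with exact Siddon ray tracing, runs a desk-scale photon Monte
    Carlo (photoelectric, Klein-Nishina Compton, Rayleigh; kerma
    approximation) scoring fibroglandular dose and entrance air kerma, and
    back-projects glandular-fraction maps into feasible breast volumes whose
    fibroglandular depth placement minimizes, maximizes, or centers the dose,
    yielding DgN bounds and a most-likely value.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
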