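Package: holoxylem
Title: Near-Field Holotomography Simulation and Morphometry of Wood Xylem
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for X-ray near-field
    nano-holotomography (NFH) of wood anatomy. Generates labelled 3D
    phantoms of conifer tracheid walls and angiosperm pit pairs with
    per-material complex refractive indices, forward-images them into
    multi-distance near-field holograms under a cone-beam geometry mapped
    to parallel beam by the Fresnel scaling theorem, and recovers the
    specimen by flat-field correction, multi-distance phase retrieval
    (contrast-transfer-function inversion plus iterative projections with
    support and range constraints), wavelet-Fourier destriping, filtered
    backprojection, seeded region growing and pit morphometry (wall
    thickness, chamber diameter, membrane thickness, slit-canal width,
    voxel-count void volume).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
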