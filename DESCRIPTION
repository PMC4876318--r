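Package: fibretex
Title: Three-Dimensional Fibre Orientation Reconstruction from Azimuthal
    WAXD Intensity Profiles
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs three-dimensional lamellar fibre orientation
    parameters from azimuthal intensity profiles I(chi) of equatorial
    reflections (such as the alpha-chitin (110) ring) in two-dimensional
    wide-angle X-ray diffraction patterns. Implements the forward
    diffraction model for planar lamellae of fibrils with a Gaussian
    in-plane orientation distribution, the exact Ewald-sphere intersection
    geometry, a fast closed-form limiting profile, Levenberg-Marquardt
    fitting of one or two coexisting fibre families (in-plane and
    out-of-plane), cake-style azimuthal regrouping of detector frames,
    synthetic-data generators with Poisson counting noise, and batch
    fitting of scan grids into fibre-orientation maps.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    tiff,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
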