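Package: xvlung
Title: X-Ray Velocimetry Analysis of Regional Lung Function
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantification chain for X-ray velocimetry (XV) of the breathing
    lung in muco-obstructive disease models. From time-resolved 3D image
    series (or precomputed displacement fields) the package estimates tissue
    motion by windowed volumetric cross-correlation, converts accumulated
    displacement into regional fractional-expansion maps, summarises each
    animal by an area-normalised expansion histogram, a least-squares
    double-Gaussian decomposition, and the heterogeneous-disease (HD) and
    clustered-disease (CD) scores, and derives whole-lung volume-time curves
    with an expiratory time constant. Preprocessing utilities provide
    mirror-symmetry auto-orientation, automatic lung segmentation,
    mask-derived lung volume, and heart-blur quality control. A seeded
    synthetic breathing-lung phantom with known ground truth supports
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    igraph,
    jsonlite,
    minpack.lm,
    RNifti
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'expansion.R'
    'globalFunction.R'
    'io.R'
    'phantom.R'
    'pipeline.R'
    'preprocess.R'
    'quantify.R'
    'utils.R'
    'velocimetry.R'
    'xvlung-package.R'
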