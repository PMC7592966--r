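Package: hepaseg
Title: Cascaded U-Net and Localized Level-Set Segmentation of Liver and
    Tumors in Contrast-Enhanced CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage segmentation of the liver and of tumors inside the
    liver envelope from contrast-enhanced abdominal CT volumes. Slices are
    prepared by Hounsfield-unit windowing, median filtering and tensor-based
    edge-enhancing anisotropic diffusion; a compact 2D U-Net trained with a
    soft-Dice loss predicts coarse per-slice probability maps; a localized
    region-based (Chan-Vese) level set with an Otsu-derived intensity gate
    refines the predicted masks slice by slice. Includes a synthetic abdominal
    CT phantom generator with ground-truth liver and tumor masks so that
    training, refinement and Dice-per-case evaluation run end to end without
    external data, plus NIfTI input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    EBImage
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
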