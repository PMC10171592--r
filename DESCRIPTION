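Package: orbitseg
Title: Encoder-Decoder Segmentation of Orbital Tissue in CT Slices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semantic segmentation of orbital tissue (eyeball, optic nerve,
    extraocular rectus muscles, lacrimal gland) in axial and coronal CT
    slices, aimed at quantitative assessment of Graves' orbitopathy. The
    core is a five-block encoder-decoder convolutional network whose decoder
    restores resolution by max-unpooling with the encoder's pooling indices
    and fuses encoder features at five scales (1, 1/2, 1/4, 1/8, 1/16)
    through skip connections; a SegNet-style baseline (indices only, no skip
    features) is included for comparison. Training uses the focal Tversky
    objective with AdamW and minimum-validation-loss checkpoint selection;
    evaluation reports Dice and IoU over repeated random splits with a
    paired t-test comparison protocol. A synthetic orbital CT phantom
    generator provides reproducible slice/mask datasets so the whole
    pipeline runs without clinical data. All network layers (convolution,
    batch normalization, pooling with argmax indices, un-pooling) and their
    gradients are implemented in C++ via RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    tiff,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
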