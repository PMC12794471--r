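Package: modse2
Title: Roto-Translation Equivariant Convolutional Networks for 2-D Medical Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete SE(2) group algebra and roto-translation equivariant
    convolutional network layers for 2-D medical image classification and
    segmentation: lifting convolutions, SE(2) group convolutions and their
    transposed (adjoint) counterparts, orientation pooling, channel
    recalibration and orientation-shared batch normalization, together with
    reference classification and segmentation architectures, hand-written
    reverse-mode gradients and an Adam trainer, classification and
    segmentation metrics, an image preprocessing pipeline, seeded synthetic
    image generators, and an equivariance verification harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    RNifti,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
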