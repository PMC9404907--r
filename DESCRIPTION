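Package: fundusreg
Title: Unsupervised Non-Rigid Registration of Retinal Fundus Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully unsupervised deformable registration of retinal fundus
    photographs. Vessel and eye-structure maps are extracted with the isotropic
    undecimated wavelet transform, a small U-shaped fully convolutional network
    predicts a dense correspondence (displacement) grid for an image pair, and a
    differentiable spatial transformer warps the moving vessel map. The coupled
    networks are trained end-to-end by maximizing normalized cross-correlation,
    so no ground-truth deformations or landmarks are required. Registered maps
    are denoised by connected-component filtering, and registration quality is
    reported as MSE, SSIM, Dice and gain coefficient. A synthetic vessel-phantom
    generator with ground-truth smooth deformations makes the whole pipeline
    testable without any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    png,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jpeg,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    tiff,
    yaml
Config/testthat/edition: 3
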