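Package: mosr
Title: Multi-Orientation U-Net Super-Resolution for Ultra-Low-Field Brain MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Reconstructs 1 mm isotropic T2-weighted brain volumes from three
    orthogonal anisotropic ultra-low-field acquisitions using a multi-orientation
    3D U-Net trained with a composite voxel-wise and slice-sampled perceptual
    loss. Includes NIfTI geometry utilities, a procedural infant-brain phantom
    generator with a forward acquisition-degradation model, stratified fold
    construction, CPU training and inference (including reduced-input inference
    by axial cloning), and a full evaluation battery: Dice overlap, region
    volumes with Pearson and Lin concordance, grey-/white-matter intensity
    differentiation, NMSE/PSNR/SSIM, and exact Wilcoxon signed-rank statistics
    with rank-biserial effect sizes.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
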