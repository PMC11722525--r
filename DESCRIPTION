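Package: wfr2star
Title: Calibrationless Model-Based Water-Fat, R2* and B0 Mapping from
    Multi-Echo Radial k-Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint estimation of water, fat, effective transverse relaxation
    rate (R2*) and B0 field maps, together with coil sensitivities, directly
    from undersampled multi-echo radial FLASH k-space. Implements the
    blip-gradient radial trajectory with small-golden-angle frame rotation,
    a six-peak fat spectrum signal model, an analytic multi-coil numerical
    phantom simulator based on the closed-form Fourier transform of ellipses,
    Kaiser-Bessel gridding NUFFT operators with exact Toeplitz embedding,
    and an iteratively regularized Gauss-Newton reconstruction with a FISTA
    inner solver combining joint l1-wavelet sparsity on the parameter maps
    with Sobolev smoothness on the field and coil maps. Voxelwise reference
    fits, ROI statistics, Bland-Altman and intra-class correlation analyses
    round out the validation pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    Rcpp,
    RNifti,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
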