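Package: cupflim
Title: Snapshot Compressive Reconstruction and Lifetime Fitting for Widefield FLIM
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstruction of a fluorescence video cube I(x,y,t) from a single
    coded, temporally sheared streak-camera measurement plus an unsheared
    time-integrated CCD image, as acquired by compressed ultrafast photography
    (CUP) for widefield fluorescence lifetime imaging (FLIM). Implements the
    linear acquisition model (mask encoding, one-row-per-frame shearing, time
    integration) with exact adjoints, a plug-and-play generalized alternating
    projection (PnP-GAP) solver with a family of total-variation priors (TV,
    TGV, 3DTV, TpV and the combined second-order lp-gradient spatio-temporal
    prior) and a pluggable second-stage denoiser, reference-quality PSNR/SSIM
    metrics, synthetic phantom and measurement generators, and per-pixel
    mono-exponential lifetime fitting with map-level statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    stats,
    tiff,
    utils
Suggests:
    MASS,
    jsonlite,
    minpack.lm,
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
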