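## Reference image-quality metrics: PSNR with the 255-peak convention and the
## global-statistics SSIM, per frame and averaged over a cube.

## the 255-scale convention: images supplied in [0,1] are placed on the
## 8-bit scale before the formula is applied
metric_scale <- function(x, y) if (max(abs(x), abs(y)) <= 1) 255 else 1

#' Peak signal-to-noise ratio
#'
#' `10 * log10(255^2 * m * n / sum((x - y)^2))` with a fixed 255 peak; inputs
#' with values in `[0, 1]` are scaled by 255 first (documented convention).
#' Identical images return `Inf`.
#'
#' @param x,y equal-shaped numeric matrices (reference and estimate).
#' @return PSNR in dB.
#' @export
psnr <- function(x, y) {
  if (!identical(dim(x), dim(y)))
    stop("images differ in shape: ", paste(dim(x), collapse = "x"), " vs ",
         paste(dim(y), collapse = "x"))
  s <- metric_scale(x, y)
  err <- sum((s * (x - y))^2)
  if (err == 0) return(Inf)
  10 * log10(255^2 * length(x) / err)
}

#' Structural similarity (global form)
#'
#' The single-window SSIM computed from whole-image means, (population)
#' variances and covariance:
#' `(2 mu_x mu_y + c1)(2 sigma_xy + c2) / ((mu_x^2 + mu_y^2 + c1)(sigma_x^2 + sigma_y^2 + c2))`.
#' Inputs in `[0, 1]` are scaled by 255; the default stabilizers are the
#' standard `c1 = (0.01 * 255)^2`, `c2 = (0.03 * 255)^2`. `windowed = TRUE`
#' gives the conventional 11x11 sliding-window mean-SSIM (valid region only)
#' for comparability with other codebases; the global form is the default.
#'
#' @param x,y equal-shaped numeric matrices.
#' @param c1,c2 stabilizing constants on the 255 scale.
#' @param windowed logical; use the 11x11 uniform-window variant.
#' @return SSIM in `[-1, 1]`; exactly 1 for identical images.
#' @export
ssim <- function(x, y, c1 = (0.01 * 255)^2, c2 = (0.03 * 255)^2,
                 windowed = FALSE) {
  if (!identical(dim(x), dim(y)))
    stop("images differ in shape: ", paste(dim(x), collapse = "x"), " vs ",
         paste(dim(y), collapse = "x"))
  s <- metric_scale(x, y)
  x <- s * x; y <- s * y
  if (windowed) return(ssim_windowed(x, y, c1, c2))
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- sum((x - mx)^2) / n
  vy <- sum((y - my)^2) / n
  cxy <- sum((x - mx) * (y - my)) / n
  ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

## uniform-window mean SSIM over the valid interior (window w x w)
ssim_windowed <- function(x, y, c1, c2, w = 11L) {
  if (nrow(x) < w || ncol(x) < w)
    stop("image smaller than the ", w, "x", w, " SSIM window")
  box <- function(m) {
    cs <- apply(m, 2, cumsum)
    cs <- rbind(0, cs)
    v <- cs[(w + 1):nrow(cs), , drop = FALSE] - cs[1:(nrow(cs) - w), , drop = FALSE]
    cs2 <- t(apply(v, 1, cumsum))
    cs2 <- cbind(0, cs2)
    (cs2[, (w + 1):ncol(cs2), drop = FALSE] -
       cs2[, 1:(ncol(cs2) - w), drop = FALSE]) / (w * w)
  }
  mx <- box(x); my <- box(y)
  vx <- box(x * x) - mx^2
  vy <- box(y * y) - my^2
  cxy <- box(x * y) - mx * my
  mean(((2 * mx * my + c1) * (2 * cxy + c2)) /
         ((mx^2 + my^2 + c1) * (vx + vy + c2)))
}

#' Per-frame quality report of a reconstruction
#'
#' PSNR and SSIM of every frame against the ground truth, plus their means.
#' The ground truth sets the dynamic-range convention: when its values lie in
#' `[0, 1]`, both cubes are placed on the 255 scale before the per-frame
#' metrics, so estimates that overshoot the truth's range (e.g. the raw
#' initialization) are measured on the same scale as well-scaled ones.
#'
#' @param cube reconstructed cube.
#' @param ground_truth reference cube, same shape.
#' @return a `quality_report` list: `per_frame_psnr`, `per_frame_ssim`,
#'   `mean_psnr`, `mean_ssim`.
#' @export
quality_report <- function(cube, ground_truth) {
  if (!identical(dim(cube), dim(ground_truth)))
    stop("cube shape ", paste(dim(cube), collapse = "x"),
         " does not match ground truth ",
         paste(dim(ground_truth), collapse = "x"))
  s <- if (max(abs(ground_truth)) <= 1) 255 else 1
  nt <- dim(cube)[3]
  pp <- ps <- numeric(nt)
  for (t in seq_len(nt)) {
    xt <- s * ground_truth[, , t]; yt <- s * cube[, , t]
    pp[t] <- psnr(xt, yt)
    ps[t] <- ssim(xt, yt)
  }
  structure(list(per_frame_psnr = pp, per_frame_ssim = ps,
                 mean_psnr = mean(pp), mean_ssim = mean(ps)),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("Quality report over ", length(x$per_frame_psnr), " frames\n", sep = "")
  cat("  mean PSNR: ", format(x$mean_psnr, digits = 5), " dB\n", sep = "")
  cat("  mean SSIM: ", format(x$mean_ssim, digits = 5), "\n", sep = "")
  invisible(x)
}
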