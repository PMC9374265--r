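## Synthetic study material: random coding masks, moving-object video
## phantoms, mono-exponential FLIM decay phantoms, and noisy measurement
## pairs — everything needed to exercise the pipeline without external data.

#' Generate a random binary coding mask
#'
#' I.i.d. Bernoulli pattern, the standard CUP encoder model. The default
#' transmittance of 25% matches the encoding density of the system this
#' package models.
#'
#' @param shape `c(ny, nx)`.
#' @param transmittance probability of an open (1) pixel, in `(0, 1]`.
#' @param seed optional integer seed for reproducibility.
#' @return a [binary_mask()].
#' @export
make_mask <- function(shape, transmittance = 0.25, seed = NULL) {
  if (transmittance <= 0 || transmittance > 1)
    stop("transmittance must lie in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  ny <- shape[1]; nx <- shape[2]
  if (transmittance == 1) return(binary_mask(matrix(1, ny, nx)))
  binary_mask(matrix(as.numeric(stats::runif(ny * nx) < transmittance), ny, nx))
}

#' Generate a moving-object video phantom
#'
#' Piecewise-constant objects translating at `speed` pixels per frame along
#' the column axis (so motion is orthogonal to the shear direction);
#' intensities in `[0, 1]`. Low-texture by default so that TV-family priors
#' are in-model; `textured = TRUE` modulates the objects with a smooth seeded
#' pattern for stress tests. The seed also jitters the starting positions so
#' different seeds give distinct phantoms.
#'
#' @param shape `c(ny, nx)`.
#' @param nt number of frames.
#' @param kind `"disk"`, `"bar"` or `"two_objects"`.
#' @param speed pixels per frame (object offsets are `round(speed * (t-1))`).
#' @param seed optional integer seed.
#' @param textured logical; add smooth intensity texture.
#' @return cube `(ny, nx, nt)` with values in `[0, 1]`.
#' @export
make_moving_phantom <- function(shape, nt, kind = c("disk", "bar", "two_objects"),
                                speed = 1, seed = NULL, textured = FALSE) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  ny <- shape[1]; nx <- shape[2]
  r <- max(2L, floor(min(ny, nx) / 6))
  travel <- round(speed * (nt - 1))
  jit <- function(span) if (!is.null(seed) && span >= 1)
    sample.int(span + 1L, 1L) - 1L else 0L
  ii <- matrix(seq_len(ny), ny, nx)
  jj <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  cube <- array(0, c(ny, nx, nt))
  stamp_disk <- function(frame, ci, cj, rad, val) {
    frame[(ii - ci)^2 + (jj - cj)^2 <= rad^2] <- val
    frame
  }
  stamp_rect <- function(frame, ci, cj, hh, hw, val) {
    sel <- abs(ii - ci) <= hh & abs(jj - cj) <= hw
    frame[sel] <- val
    frame
  }
  slack_y <- ny - 2L * r - 2L
  slack_x <- nx - 2L * r - 2L - max(travel, 0)
  if (slack_x < 0)
    stop("object trajectory exceeds the frame: reduce speed or nt")
  ci <- r + 1L + jit(slack_y)
  cj0 <- r + 1L + jit(slack_x)
  for (t in seq_len(nt)) {
    off <- round(speed * (t - 1))
    f <- matrix(0, ny, nx)
    if (kind == "disk") {
      f <- stamp_disk(f, ci, cj0 + off, r, 1.0)
    } else if (kind == "bar") {
      f <- stamp_rect(f, ci, cj0 + off, r + 1L, max(1L, r %/% 2L), 0.8)
    } else {
      f <- stamp_disk(f, ci, cj0 + off, r, 1.0)
      ci2 <- ny - r - jit(slack_y)
      f <- stamp_rect(f, ci2, nx - r - off, r - 1L, r - 1L, 0.6)
    }
    cube[, , t] <- f
  }
  if (textured) {
    tex <- 0.85 + 0.15 * sin(2 * pi * ii / ny) * cos(2 * pi * jj / nx)
    cube <- cube * as.vector(tex)
  }
  video_cube(cube)
}

#' Specification of a FLIM decay phantom
#'
#' Regions of constant amplitude and lifetime on an `(ny, nx)` grid; each
#' covered pixel decays as `A * exp(-t / tau)` sampled at `t = (k-1) * dt`
#' (delta-function instrument response).
#'
#' @param shape `c(ny, nx)`.
#' @param nt number of frames.
#' @param dt frame interval in seconds (default 330 ps).
#' @param regions list of regions; each a list with `type` (`"rect"` or
#'   `"disk"`), geometry (`rows`/`cols` index vectors for rect, `center` and
#'   `radius` for disk), amplitude `A` (> 0) and lifetime `tau` in seconds
#'   (> 0).
#' @param noise `"gaussian"` (default), `"none"` or `"poisson"`.
#' @param sigma Gaussian noise s.d. as a fraction of the peak amplitude
#'   (default 0.01, the low-noise regime).
#' @param scale Poisson photon scale (expected counts per unit intensity).
#' @param seed optional integer seed.
#' @return a `flim_phantom_spec` list.
#' @export
flim_phantom_spec <- function(shape, nt, dt = 330e-12, regions,
                              noise = c("gaussian", "none", "poisson"),
                              sigma = 0.01, scale = 1000, seed = NULL) {
  noise <- match.arg(noise)
  if (dt <= 0) stop("dt must be > 0")
  for (rg in regions) {
    if (is.null(rg$tau) || rg$tau <= 0) stop("every region needs tau > 0")
    if (is.null(rg$A) || rg$A <= 0) stop("every region needs amplitude A > 0")
  }
  structure(list(shape = shape, nt = as.integer(nt), dt = dt,
                 regions = regions, noise = noise, sigma = sigma,
                 scale = scale, seed = seed),
            class = "flim_phantom_spec")
}

region_pixels <- function(rg, ny, nx) {
  sel <- matrix(FALSE, ny, nx)
  if (identical(rg$type, "disk")) {
    ii <- matrix(seq_len(ny), ny, nx)
    jj <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
    sel[(ii - rg$center[1])^2 + (jj - rg$center[2])^2 <= rg$radius^2] <- TRUE
  } else {
    sel[rg$rows, rg$cols] <- TRUE
  }
  sel
}

#' Generate a FLIM decay phantom with ground truth
#'
#' @param spec a [flim_phantom_spec()].
#' @return list with `cube` (the decay video) and `truth` (a `lifetime_map`
#'   with per-pixel amplitude, lifetime and validity of the generating model).
#' @export
make_flim_phantom <- function(spec) {
  stopifnot(inherits(spec, "flim_phantom_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  ny <- spec$shape[1]; nx <- spec$shape[2]; nt <- spec$nt
  tvec <- (seq_len(nt) - 1) * spec$dt
  cube <- array(0, c(ny, nx, nt))
  tau <- amp <- matrix(NA_real_, ny, nx)
  valid <- matrix(FALSE, ny, nx)
  for (rg in spec$regions) {
    sel <- region_pixels(rg, ny, nx)
    tau[sel] <- rg$tau; amp[sel] <- rg$A; valid <- valid | sel
    decay <- rg$A * exp(-tvec / rg$tau)
    for (t in seq_len(nt)) {
      f <- cube[, , t]; f[sel] <- decay[t]; cube[, , t] <- f
    }
  }
  peak <- max(cube)
  if (spec$noise == "gaussian" && spec$sigma > 0) {
    cube <- cube + array(stats::rnorm(length(cube), 0, spec$sigma * peak),
                         dim(cube))
  } else if (spec$noise == "poisson") {
    cube <- array(stats::rpois(length(cube), pmax(cube, 0) * spec$scale),
                  dim(cube)) / spec$scale
  }
  truth <- structure(list(tau = tau, amplitude = amp, valid = valid,
                          rsq = ifelse(valid, 1, NA_real_), dt = spec$dt),
                     class = "lifetime_map")
  list(cube = video_cube(cube, dt = spec$dt), truth = truth)
}

#' Simulate a CUP acquisition of a cube
#'
#' Applies the two forward channels and (optionally) measurement noise:
#' Gaussian with s.d. `sigma` times each channel's peak, or Poisson photon
#' noise at `scale` expected counts per unit intensity. Noiseless mode is
#' exact.
#'
#' @param cube 3D array `(ny, nx, nt)`.
#' @param mask 0/1 coding mask.
#' @param noise `"gaussian"` (default, the low-noise regime), `"none"` or
#'   `"poisson"`.
#' @param sigma Gaussian noise fraction of peak (default 0.01).
#' @param scale Poisson photon scale.
#' @param seed optional integer seed.
#' @return a [measurement_pair()].
#' @export
simulate_acquisition <- function(cube, mask, noise = c("gaussian", "none", "poisson"),
                                 sigma = 0.01, scale = 1000, seed = NULL) {
  noise <- match.arg(noise)
  if (!is.null(seed)) set.seed(seed)
  e_s <- forward_streak(cube, mask)
  e_c <- forward_ccd(cube)
  if (noise == "gaussian" && sigma > 0) {
    e_s <- e_s + matrix(stats::rnorm(length(e_s), 0, sigma * max(abs(e_s))),
                        nrow(e_s))
    e_c <- e_c + matrix(stats::rnorm(length(e_c), 0, sigma * max(abs(e_c))),
                        nrow(e_c))
  } else if (noise == "poisson") {
    e_s <- matrix(stats::rpois(length(e_s), pmax(e_s, 0) * scale), nrow(e_s)) / scale
    e_c <- matrix(stats::rpois(length(e_c), pmax(e_c, 0) * scale), nrow(e_c)) / scale
  }
  measurement_pair(e_s, e_c)
}
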