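#' Validate a video cube
#'
#' A video cube is the 3D scene `I(x, y, t)` stored as a numeric array indexed
#' `(row, column, frame)`. All indexing in the package is 1-based and the frame
#' interval `dt` (seconds) is carried as an attribute; the default of 330 ps is
#' the streak-camera time resolution of the system the package models.
#'
#' @param data numeric 3D array, shape `(ny, nx, nt)`.
#' @param dt frame interval in seconds (> 0).
#' @return the validated array with attribute `dt`.
#' @export
video_cube <- function(data, dt = 330e-12) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("video cube must be a 3D array (ny, nx, nt); got dims ",
         paste(dim(data), collapse = "x"))
  if (!all(is.finite(data))) stop("video cube contains non-finite values")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a single positive number of seconds")
  attr(data, "dt") <- dt
  data
}

#' Validate a binary coding mask
#'
#' The spatial encoder pattern applied to every frame (the diagonal of the
#' coding operator). Entries must be exactly 0 or 1.
#'
#' @param data numeric matrix of 0/1 entries.
#' @return the validated matrix with attribute `transmittance` (fraction of 1s).
#' @export
binary_mask <- function(data) {
  if (!is.matrix(data)) stop("mask must be a matrix")
  if (!all(data %in% c(0, 1))) stop("mask entries must be exactly 0 or 1")
  attr(data, "transmittance") <- mean(data)
  data
}

#' Bundle the two measurement channels
#'
#' `e_s` is the streak-camera image: the coded cube sheared down the row axis
#' by one row per frame and summed over frames, so it has `ny + nt - 1` rows.
#' `e_c` is the external CCD image: the plain time integral, `ny` rows. The
#' number of frames is implied by the row difference.
#'
#' @param e_s streak measurement, matrix `(ny + nt - 1, nx)`.
#' @param e_c CCD measurement, matrix `(ny, nx)`.
#' @return a `measurement_pair` list with elements `e_s`, `e_c`, `nt`.
#' @export
measurement_pair <- function(e_s, e_c) {
  if (!is.matrix(e_s) || !is.matrix(e_c)) stop("measurements must be matrices")
  if (ncol(e_s) != ncol(e_c))
    stop("column counts differ: e_s has ", ncol(e_s), ", e_c has ", ncol(e_c))
  nt <- nrow(e_s) - nrow(e_c) + 1L
  if (nt < 1L)
    stop("e_s must have at least as many rows as e_c (sheared canvas); got ",
         nrow(e_s), " vs ", nrow(e_c))
  if (!all(is.finite(e_s)) || !all(is.finite(e_c)))
    stop("measurements contain non-finite values")
  structure(list(e_s = e_s, e_c = e_c, nt = nt), class = "measurement_pair")
}

#' @export
print.measurement_pair <- function(x, ...) {
  cat("CUP measurement pair\n")
  cat("  streak e_s: ", nrow(x$e_s), " x ", ncol(x$e_s), "\n", sep = "")
  cat("  CCD    e_c: ", nrow(x$e_c), " x ", ncol(x$e_c),
      "  (nt = ", x$nt, ")\n", sep = "")
  invisible(x)
}

#' Spatially encode a cube with a binary mask
#'
#' Multiplies every frame elementwise by the mask (operator T of the
#' acquisition model).
#'
#' @param cube 3D array `(ny, nx, nt)`.
#' @param mask 0/1 matrix `(ny, nx)`.
#' @return encoded cube, same shape.
#' @export
encode_cube <- function(cube, mask) {
  d <- dim(cube)
  if (nrow(mask) != d[1] || ncol(mask) != d[2])
    stop("mask shape ", nrow(mask), "x", ncol(mask),
         " does not match frame shape ", d[1], "x", d[2])
  cube * as.vector(mask)  # mask recycles over the frame axis
}

#' Temporally shear a cube
#'
#' Frame t is shifted down the row axis by t - 1 rows onto an enlarged canvas
#' of `ny + nt - 1` rows (operator S; the streak sweep, one detector row per
#' frame, top to bottom). Zero padding; no signal is clipped.
#'
#' @param cube 3D array `(ny, nx, nt)`.
#' @return sheared cube, shape `(ny + nt - 1, nx, nt)`.
#' @export
shear_cube <- function(cube) {
  d <- dim(cube); ny <- d[1]; nx <- d[2]; nt <- d[3]
  out <- array(0, c(ny + nt - 1L, nx, nt))
  for (t in seq_len(nt))
    out[t:(t + ny - 1L), , t] <- cube[, , t]
  out
}

#' Integrate a cube over time
#'
#' Elementwise sum over the frame axis (operator C).
#'
#' @param cube 3D array.
#' @return matrix of per-pixel frame sums.
#' @export
integrate_cube <- function(cube) {
  d <- dim(cube)
  matrix(rowSums(matrix(cube, d[1] * d[2], d[3])), d[1], d[2])
}

#' Streak-channel forward operator
#'
#' The full acquisition seen by the streak camera: encode, shear, integrate.
#' Linear in the cube.
#'
#' @inheritParams encode_cube
#' @return streak measurement `e_s`, matrix `(ny + nt - 1, nx)`.
#' @export
forward_streak <- function(cube, mask) {
  d <- dim(cube); ny <- d[1]; nx <- d[2]; nt <- d[3]
  if (nrow(mask) != ny || ncol(mask) != nx)
    stop("mask shape ", nrow(mask), "x", ncol(mask),
         " does not match frame shape ", ny, "x", nx)
  out <- matrix(0, ny + nt - 1L, nx)
  for (t in seq_len(nt))
    out[t:(t + ny - 1L), ] <- out[t:(t + ny - 1L), ] + cube[, , t] * mask
  out
}

#' CCD-channel forward operator
#'
#' The external CCD sees the unsheared, uncoded time integral of the cube.
#'
#' @param cube 3D array.
#' @return CCD measurement `e_c`, matrix `(ny, nx)`.
#' @export
forward_ccd <- function(cube) integrate_cube(cube)

#' Adjoint of the streak-channel forward operator
#'
#' For every cube x and measurement y,
#' `sum(forward_streak(x, mask) * y) == sum(x * adjoint_streak(y, mask, nt))`.
#' Frame t of the result is the measurement window starting at row t,
#' re-masked.
#'
#' @param e_s streak-shaped matrix `(ny + nt - 1, nx)`.
#' @param mask 0/1 matrix `(ny, nx)`.
#' @param nt number of frames.
#' @return cube `(ny, nx, nt)`.
#' @export
adjoint_streak <- function(e_s, mask, nt) {
  ny <- nrow(e_s) - nt + 1L
  if (ny != nrow(mask) || ncol(e_s) != ncol(mask))
    stop("e_s shape ", nrow(e_s), "x", ncol(e_s),
         " inconsistent with mask ", nrow(mask), "x", ncol(mask),
         " and nt = ", nt)
  out <- array(0, c(ny, ncol(e_s), nt))
  for (t in seq_len(nt))
    out[, , t] <- e_s[t:(t + ny - 1L), ] * mask
  out
}

#' Adjoint of the CCD-channel forward operator
#'
#' Broadcasts the CCD image to every frame (adjoint of the frame sum).
#'
#' @param e_c matrix `(ny, nx)`.
#' @param nt number of frames.
#' @return cube `(ny, nx, nt)`.
#' @export
adjoint_ccd <- function(e_c, nt) {
  array(rep(e_c, nt), c(nrow(e_c), ncol(e_c), nt))
}

#' Diagonal of the streak-channel Gram operator
#'
#' For this forward model `A_s A_s'` is diagonal; entry (r, c) counts (as the
#' sum of squared sheared mask values) how many coded frames land on
#' measurement pixel (r, c). Used by the GAP Euclidean projection; entries
#' below 1e-12 mean "no measurement there".
#'
#' @param mask 0/1 matrix `(ny, nx)`.
#' @param nt number of frames.
#' @return matrix `(ny + nt - 1, nx)`.
#' @export
gram_diagonal_streak <- function(mask, nt) {
  ny <- nrow(mask)
  out <- matrix(0, ny + nt - 1L, ncol(mask))
  m2 <- mask^2
  for (t in seq_len(nt))
    out[t:(t + ny - 1L), ] <- out[t:(t + ny - 1L), ] + m2
  out
}
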