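## Independent dense-matrix oracles, built by explicit loops from the
## definitions of the acquisition operators (never from the package's own
## implementation). Vectorization order: (row, column, frame), column-major.

vox_index <- function(i, j, t, ny, nx) i + (j - 1L) * ny + (t - 1L) * ny * nx

## dense streak operator A_s: measurement pixel (r, c) receives cube voxel
## (i, j, t) iff r = i + t - 1, c = j, weighted by the mask
dense_streak_matrix <- function(mask, nt) {
  ny <- nrow(mask); nx <- ncol(mask)
  nr <- ny + nt - 1L
  A <- matrix(0, nr * nx, ny * nx * nt)
  for (t in seq_len(nt)) for (j in seq_len(nx)) for (i in seq_len(ny)) {
    r <- i + t - 1L
    A[r + (j - 1L) * nr, vox_index(i, j, t, ny, nx)] <- mask[i, j]
  }
  A
}

## dense CCD operator A_c: plain frame sum
dense_ccd_matrix <- function(ny, nx, nt) {
  A <- matrix(0, ny * nx, ny * nx * nt)
  for (t in seq_len(nt)) for (j in seq_len(nx)) for (i in seq_len(ny)) {
    A[i + (j - 1L) * ny, vox_index(i, j, t, ny, nx)] <- 1
  }
  A
}

## brute-force composite prior value by explicit loops over the stencil;
## differences use zero beyond-edge values, so the order-2 stencil is the
## composition of two zero-padded first differences (at the second slice it
## reduces to the first difference)
loop_prior_value <- function(u, p, tau, order) {
  d <- dim(u); ny <- d[1]; nx <- d[2]; nt <- d[3]
  stencil <- function(a, b, c, idx) {        # value, value-1, value-2
    if (order == 1) {
      if (idx >= 2) a - b else 0
    } else {
      if (idx >= 3) a - 2 * b + c else if (idx == 2) a - b else 0
    }
  }
  s <- 0
  for (i in seq_len(ny)) for (j in seq_len(nx)) for (t in seq_len(nt)) {
    di <- stencil(u[i, j, t], if (i >= 2) u[i - 1, j, t] else 0,
                  if (i >= 3) u[i - 2, j, t] else 0, i)
    dj <- stencil(u[i, j, t], if (j >= 2) u[i, j - 1, t] else 0,
                  if (j >= 3) u[i, j - 2, t] else 0, j)
    dt_ <- stencil(u[i, j, t], if (t >= 2) u[i, j, t - 1] else 0,
                   if (t >= 3) u[i, j, t - 2] else 0, t)
    s <- s + abs(di)^p + abs(dj)^p + tau * abs(dt_)^p
  }
  s^(1 / p)
}

random_cube <- function(ny, nx, nt, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(stats::rnorm(ny * nx * nt), c(ny, nx, nt))
}

checkerboard_mask <- function(ny, nx) {
  binary_mask(outer(seq_len(ny), seq_len(nx), function(i, j) (i + j) %% 2))
}
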