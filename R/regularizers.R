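## TV-family priors: finite-difference transforms on the (row, column, frame)
## axes, the lp (0 < p <= 1) composite functional, and the dual clip update
## used as the prior's denoising step inside the PnP-GAP loop.

## forward difference along one axis; the first slice is structurally zero
## (zero beyond-edge values, consistent with axis_diff_adjoint below)
axis_diff <- function(u, axis) {
  d <- array(0, dim(u))
  n <- dim(u)[axis]
  if (n < 2L) return(d)
  i2 <- 2:n; i1 <- 1:(n - 1L)
  if (axis == 1L) d[i2, , ] <- u[i2, , , drop = FALSE] - u[i1, , , drop = FALSE]
  else if (axis == 2L) d[, i2, ] <- u[, i2, , drop = FALSE] - u[, i1, , drop = FALSE]
  else d[, , i2] <- u[, , i2, drop = FALSE] - u[, , i1, drop = FALSE]
  d
}

## exact transpose of axis_diff (slice 1 of z never contributes because
## axis_diff leaves it structurally zero)
axis_diff_adjoint <- function(z, axis) {
  a <- array(0, dim(z))
  n <- dim(z)[axis]
  if (n < 2L) return(a)
  i2 <- 2:n; i1 <- 1:(n - 1L)
  if (axis == 1L) {
    a[i1, , ] <- -z[i2, , , drop = FALSE]
    a[i2, , ] <- a[i2, , , drop = FALSE] + z[i2, , , drop = FALSE]
  } else if (axis == 2L) {
    a[, i1, ] <- -z[, i2, , drop = FALSE]
    a[, i2, ] <- a[, i2, , drop = FALSE] + z[, i2, , drop = FALSE]
  } else {
    a[, , i1] <- -z[, , i2, drop = FALSE]
    a[, , i2] <- a[, , i2, drop = FALSE] + z[, , i2, drop = FALSE]
  }
  a
}

nth_diff <- function(u, axis, order) {
  d <- axis_diff(u, axis)
  if (order == 2L) d <- axis_diff(d, axis)
  d
}

nth_diff_adjoint <- function(z, axis, order) {
  a <- axis_diff_adjoint(z, axis)
  if (order == 2L) a <- axis_diff_adjoint(a, axis)
  a
}

#' First-order gradient field of a cube
#'
#' Forward differences along rows, columns and frames; the leading
#' row/column/frame of each component is zero (the stencil has zero
#' beyond-edge values).
#'
#' @param cube 3D array `(ny, nx, nt)`.
#' @return list with components `d_i` (rows), `d_j` (columns), `d_t` (frames),
#'   each the same shape as `cube`.
#' @export
grad_first <- function(cube) {
  list(d_i = axis_diff(cube, 1L), d_j = axis_diff(cube, 2L),
       d_t = axis_diff(cube, 3L))
}

#' Second-order gradient field of a cube
#'
#' Difference-of-differences along each axis; linear ramps map to zero away
#' from the boundary.
#'
#' @inheritParams grad_first
#' @return list with components `d_i`, `d_j`, `d_t`.
#' @export
grad_second <- function(cube) {
  list(d_i = nth_diff(cube, 1L, 2L), d_j = nth_diff(cube, 2L, 2L),
       d_t = nth_diff(cube, 3L, 2L))
}

#' Configuration of a TV-family prior
#'
#' @param p exponent of the lp gradient norm, in (0, 1]; p = 1 is classical
#'   (convex) TV, p < 1 is the sharper non-convex variant.
#' @param tau temporal weight in `[0, 1]`: 0 ignores the frame axis, 1 weights
#'   it like the spatial axes. Default 0.2.
#' @param lambda_ regularization weight (>= 0; 0 disables the prior).
#' @param alpha dual step size (> 0); the dual update uses step `1/alpha`.
#'   `NULL` (default) picks the stability bound of the configured stencil,
#'   `sum over active axes of 4^order`: 8 for first-order spatial, 12 with the
#'   temporal axis, 32/48 for the second-order variants.
#' @param order 1 (first differences) or 2 (second differences).
#' @param use_time logical; include the temporal component (with weight `tau`).
#' @param n_inner number of dual sweeps per denoising call (>= 1).
#' @param isotropic logical; for p = 1 only, use the isotropic (rooted
#'   sum-of-squares) coupling of the axes instead of the per-axis sum.
#' @return a `prior_config` list.
#' @export
prior_config <- function(p = 0.8, tau = 0.2, lambda_ = 0.07, alpha = NULL,
                         order = 2L, use_time = TRUE, n_inner = 1L,
                         isotropic = FALSE) {
  if (!(p > 0 && p <= 1)) stop("p must lie in (0, 1]; got ", p)
  if (tau < 0 || tau > 1) stop("tau must lie in [0, 1]; got ", tau)
  if (lambda_ < 0) stop("lambda_ must be >= 0")
  n_axes <- 2 + (isTRUE(use_time) && tau > 0)
  if (is.null(alpha)) alpha <- n_axes * 4^order  # ||Psi' Psi|| stability bound
  if (alpha <= 0) stop("alpha must be > 0")
  if (!order %in% c(1L, 2L)) stop("order must be 1 or 2")
  if (n_inner < 1L) stop("n_inner must be >= 1")
  if (isotropic && p != 1) stop("isotropic coupling is defined for p = 1 only")
  structure(list(p = p, tau = tau, lambda_ = lambda_, alpha = alpha,
                 order = as.integer(order), use_time = use_time,
                 n_inner = as.integer(n_inner), isotropic = isotropic),
            class = "prior_config")
}

#' Named prior presets
#'
#' The five members of the TV family as fixed configurations:
#' `"tv"` (order 1, p = 1, no time), `"tgv"` (order 2, p = 1, no time),
#' `"3dtv"` (order 1, p = 1, temporal weight tau), `"tpv"` (order 1, p < 1,
#' no time) and `"3dtgpv"` (order 2, p < 1, temporal weight tau) — the
#' combined second-order spatio-temporal lp-gradient prior.
#'
#' @param name one of `"tv"`, `"tgv"`, `"3dtv"`, `"tpv"`, `"3dtgpv"`
#'   (case-insensitive).
#' @param p exponent used by the p < 1 presets (default 0.8).
#' @param tau temporal weight used by the spatio-temporal presets (default 0.2).
#' @param lambda_ regularization weight (default 0.07).
#' @return a [prior_config()].
#' @export
named_prior <- function(name, p = 0.8, tau = 0.2, lambda_ = 0.07) {
  switch(tolower(name),
    tv     = prior_config(p = 1, tau = 0, lambda_ = lambda_, order = 1L,
                          use_time = FALSE),
    tgv    = prior_config(p = 1, tau = 0, lambda_ = lambda_, order = 2L,
                          use_time = FALSE),
    `3dtv` = prior_config(p = 1, tau = tau, lambda_ = lambda_, order = 1L,
                          use_time = TRUE),
    tpv    = prior_config(p = p, tau = 0, lambda_ = lambda_, order = 1L,
                          use_time = FALSE),
    `3dtgpv` = prior_config(p = p, tau = tau, lambda_ = lambda_, order = 2L,
                            use_time = TRUE),
    stop("unknown prior '", name,
         "'; expected one of tv, tgv, 3dtv, tpv, 3dtgpv")
  )
}

## temporal weight inside the transform: the p-sum sees tau * |d_t|^p, so the
## linear operator carries tau^(1/p) on the frame axis
temporal_weight <- function(cfg) {
  if (isTRUE(cfg$use_time) && cfg$tau > 0) cfg$tau^(1 / cfg$p) else 0
}

## the sparsifying transform Psi of the configured prior (3 components)
psi_apply <- function(u, cfg) {
  wt <- temporal_weight(cfg)
  list(d_i = nth_diff(u, 1L, cfg$order),
       d_j = nth_diff(u, 2L, cfg$order),
       d_t = if (wt > 0) wt * nth_diff(u, 3L, cfg$order) else array(0, dim(u)))
}

## exact adjoint of psi_apply
psi_adjoint <- function(z, cfg) {
  wt <- temporal_weight(cfg)
  a <- nth_diff_adjoint(z$d_i, 1L, cfg$order) +
       nth_diff_adjoint(z$d_j, 2L, cfg$order)
  if (wt > 0) a <- a + wt * nth_diff_adjoint(z$d_t, 3L, cfg$order)
  a
}

#' Value of the composite gradient prior
#'
#' Computes `( sum |D_i u|^p + |D_j u|^p + tau |D_t u|^p )^(1/p)` with D the
#' first- or second-order difference operator selected by the configuration.
#' Non-negative; zero iff every penalized difference vanishes. With
#' `isotropic = TRUE` (p = 1 only) the axes are coupled under a square root
#' instead of summed per axis.
#'
#' @param cube 3D array.
#' @param cfg a [prior_config()].
#' @return scalar prior value.
#' @export
composite_prior_value <- function(cube, cfg) {
  stopifnot(inherits(cfg, "prior_config"))
  g <- psi_apply(cube, cfg)
  if (isTRUE(cfg$isotropic)) {
    return(sum(sqrt(g$d_i^2 + g$d_j^2 + g$d_t^2)))
  }
  s <- sum(abs(g$d_i)^cfg$p) + sum(abs(g$d_j)^cfg$p) + sum(abs(g$d_t)^cfg$p)
  s^(1 / cfg$p)
}

#' Magnitude clip
#'
#' `clip(sigma, T)` returns `sigma` where `|sigma| <= T` and `T * sign(sigma)`
#' otherwise, elementwise; `T` may be a scalar or an array of per-element
#' thresholds. This is the dual projection of the l1-gradient prior.
#'
#' @param sigma numeric array.
#' @param threshold non-negative scalar or congruent array.
#' @return clipped array.
#' @export
clip_magnitude <- function(sigma, threshold) {
  pmin(pmax(sigma, -threshold), threshold)
}

## per-component clip thresholds: lambda/2 for p = 1; for p < 1 an iteratively
## reweighted threshold lambda/2 * w, w = (|Psi v| + eps)^(p-1) normalized to
## max 1 over the active components, so large gradients (edges) are penalized
## less — the non-convex lp behaviour retained within the clip form
dual_thresholds <- function(g, cfg) {
  half <- cfg$lambda_ / 2
  wt <- temporal_weight(cfg)
  if (cfg$p == 1) {
    return(list(d_i = half, d_j = half, d_t = if (wt > 0) half else 0))
  }
  gmax <- if (wt > 0) max(abs(g$d_i), abs(g$d_j), abs(g$d_t))
          else max(abs(g$d_i), abs(g$d_j))
  eps <- 1e-6 * gmax + 1e-12
  wi <- (abs(g$d_i) + eps)^(cfg$p - 1)
  wj <- (abs(g$d_j) + eps)^(cfg$p - 1)
  if (wt > 0) {
    wtt <- (abs(g$d_t) + eps)^(cfg$p - 1)
    m <- max(wi, wj, wtt)
    list(d_i = half * wi / m, d_j = half * wj / m, d_t = half * wtt / m)
  } else {
    m <- max(wi, wj)
    list(d_i = half * wi / m, d_j = half * wj / m, d_t = 0)
  }
}

zero_dual <- function(u, cfg) {
  z0 <- array(0, dim(u))
  list(d_i = z0, d_j = z0, d_t = z0)
}

#' Prior denoising step (dual clip update)
#'
#' One denoising call of the PnP loop: `n_inner` dual sweeps
#' `z <- clip(z + (1/alpha) Psi v, lambda/2)` with `v = u - Psi' z`, followed
#' by the primal step `v1 = u - Psi' z`. The dual state is warm-started across
#' outer iterations by passing the returned `z` back in. With `lambda_ = 0`
#' the threshold is zero, the dual collapses and `u` is returned unchanged.
#'
#' @param u cube to denoise.
#' @param z dual state as returned by a previous call, or `NULL` to start from
#'   zero.
#' @param cfg a [prior_config()].
#' @return list with `v` (denoised cube) and `z` (updated dual state, every
#'   entry within the clip threshold).
#' @export
tgpv_denoise <- function(u, z = NULL, cfg = prior_config()) {
  stopifnot(inherits(cfg, "prior_config"))
  if (is.null(z)) z <- zero_dual(u, cfg)
  if (!identical(dim(z$d_i), dim(u)))
    stop("dual state shape ", paste(dim(z$d_i), collapse = "x"),
         " does not match cube shape ", paste(dim(u), collapse = "x"))
  if (cfg$lambda_ == 0) return(list(v = u, z = zero_dual(u, cfg)))
  inva <- 1 / cfg$alpha
  for (k in seq_len(cfg$n_inner)) {
    v <- u - psi_adjoint(z, cfg)
    g <- psi_apply(v, cfg)
    thr <- dual_thresholds(g, cfg)
    z <- list(d_i = clip_magnitude(z$d_i + inva * g$d_i, thr$d_i),
              d_j = clip_magnitude(z$d_j + inva * g$d_j, thr$d_j),
              d_t = clip_magnitude(z$d_t + inva * g$d_t, thr$d_t))
  }
  list(v = u - psi_adjoint(z, cfg), z = z)
}
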