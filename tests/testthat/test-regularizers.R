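test_that("first-order gradient matches the loop stencil and ramp cases", {
  const <- array(3.7, c(4, 4, 3))
  g <- grad_first(const)
  expect_true(all(g$d_i == 0) && all(g$d_j == 0) && all(g$d_t == 0))

  ramp <- array(rep(1:4, 4 * 3), c(4, 4, 3))  # u(i,j,t) = i
  g <- grad_first(ramp)
  expect_true(all(g$d_i[2:4, , ] == 1))
  expect_true(all(g$d_i[1, , ] == 0))
  expect_true(all(g$d_j == 0) && all(g$d_t == 0))

  u <- random_cube(4, 4, 3, seed = 1)
  g <- grad_first(u)
  for (i in 1:4) for (j in 1:4) for (t in 1:3) {
    expect_equal(g$d_i[i, j, t], if (i > 1) u[i, j, t] - u[i - 1, j, t] else 0)
    expect_equal(g$d_t[i, j, t], if (t > 1) u[i, j, t] - u[i, j, t - 1] else 0)
  }
})

test_that("second-order gradient annihilates ramps and matches quadratics", {
  ramp <- array(rep(1:5, 4 * 3), c(5, 4, 3))          # affine in i
  g <- grad_second(ramp)
  expect_true(all(g$d_i[3:5, , ] == 0))
  quad <- array(rep((1:5)^2, 4 * 3), c(5, 4, 3))      # u = i^2
  g <- grad_second(quad)
  expect_true(all(g$d_i[3:5, , ] == 2))
  u <- random_cube(4, 4, 4, seed = 2)
  g <- grad_second(u)
  for (i in 3:4) for (j in 1:4) for (t in 1:4)
    expect_equal(g$d_i[i, j, t], u[i, j, t] - 2 * u[i - 1, j, t] + u[i - 2, j, t])
})

test_that("composite prior value matches hand and brute-force sums", {
  cfg_tv <- named_prior("tv")
  const <- array(2, c(3, 3, 2))
  expect_equal(composite_prior_value(const, cfg_tv), 0)

  # 2x2x1 cube [[0,1],[0,1]]: two unit column differences, anisotropic TV = 2
  step <- array(c(0, 0, 1, 1), c(2, 2, 1))
  expect_equal(composite_prior_value(step, cfg_tv), 2)

  u <- random_cube(3, 3, 2, seed = 3)
  for (nm in c("tv", "tgv", "3dtv", "tpv", "3dtgpv")) {
    cfg <- named_prior(nm)
    tau_eff <- if (cfg$use_time) cfg$tau else 0
    expect_equal(composite_prior_value(u, cfg),
                 loop_prior_value(u, cfg$p, tau_eff, cfg$order),
                 tolerance = 1e-12, label = nm)
  }
})

test_that("named presets select the documented order, exponent and time weight", {
  expect_mapequal(named_prior("tv")[c("order", "p", "tau")],
                  list(order = 1L, p = 1, tau = 0))
  expect_mapequal(named_prior("tgv")[c("order", "p", "tau")],
                  list(order = 2L, p = 1, tau = 0))
  expect_mapequal(named_prior("3dtv")[c("order", "p", "tau")],
                  list(order = 1L, p = 1, tau = 0.2))
  expect_mapequal(named_prior("tpv")[c("order", "p", "tau")],
                  list(order = 1L, p = 0.8, tau = 0))
  expect_mapequal(named_prior("3dtgpv")[c("order", "p", "tau")],
                  list(order = 2L, p = 0.8, tau = 0.2))
  expect_error(named_prior("bm3d"), "unknown prior")
})

test_that("clip keeps small values, saturates large ones, handles zero threshold", {
  expect_equal(clip_magnitude(0.5, 1), 0.5)
  expect_equal(clip_magnitude(-3, 1), -1)
  expect_equal(clip_magnitude(0, 0), 0)
  x <- c(-2, -0.3, 0, 0.3, 2)
  expect_equal(clip_magnitude(x, 0.5), c(-0.5, -0.3, 0, 0.3, 0.5))
})

test_that("the prior transform and its adjoint form an exact pair", {
  set.seed(4)
  for (nm in c("tv", "tgv", "3dtv", "3dtgpv")) {
    cfg <- named_prior(nm)
    u <- random_cube(5, 4, 3)
    z <- list(d_i = random_cube(5, 4, 3), d_j = random_cube(5, 4, 3),
              d_t = random_cube(5, 4, 3))
    g <- cupflim:::psi_apply(u, cfg)
    lhs <- sum(g$d_i * z$d_i) + sum(g$d_j * z$d_j) + sum(g$d_t * z$d_t)
    rhs <- sum(u * cupflim:::psi_adjoint(z, cfg))
    expect_lt(abs(lhs - rhs), 1e-10 * max(abs(lhs), 1))
  }
})

test_that("denoising is the identity at lambda 0 and on constant cubes", {
  u <- random_cube(6, 6, 3, seed = 5)
  cfg <- named_prior("3dtgpv")
  cfg$lambda_ <- 0
  out <- tgpv_denoise(u, NULL, cfg)
  expect_identical(out$v, u)

  const <- array(1.5, c(6, 6, 3))
  out <- tgpv_denoise(const, NULL, named_prior("tv"))
  expect_equal(out$v, const)
})

test_that("TV denoising reduces total variation of a noisy step image", {
  set.seed(6)
  u <- array(0, c(12, 12, 1))
  u[, 7:12, 1] <- 1
  u <- u + array(rnorm(144, 0, 0.05), dim(u))
  cfg <- named_prior("tv")
  v <- u; z <- NULL
  for (k in 1:20) { out <- tgpv_denoise(v, z, cfg); v <- out$v; z <- out$z }
  expect_lt(composite_prior_value(v, cfg), composite_prior_value(u, cfg))
})

test_that("dual iterates stay within the clip threshold", {
  u <- random_cube(6, 6, 4, seed = 7)
  for (nm in c("tv", "3dtgpv")) {
    cfg <- named_prior(nm)
    z <- NULL
    for (k in 1:5) {
      out <- tgpv_denoise(u, z, cfg)
      z <- out$z
      expect_lte(max(abs(z$d_i), abs(z$d_j), abs(z$d_t)), cfg$lambda_ / 2)
    }
  }
})

test_that("p = 1 denoising is scale-covariant when lambda scales with the input", {
  u <- random_cube(5, 5, 3, seed = 8)
  cfg <- named_prior("tv")
  out1 <- tgpv_denoise(u, NULL, cfg)
  cfg5 <- cfg; cfg5$lambda_ <- 5 * cfg$lambda_
  out5 <- tgpv_denoise(5 * u, NULL, cfg5)
  expect_equal(out5$v, 5 * out1$v, tolerance = 1e-12)
})

test_that("combined prior at p=1, tau=1 decomposes into TGV plus the temporal term", {
  u <- random_cube(4, 4, 4, seed = 9)
  full <- prior_config(p = 1, tau = 1, order = 2L, use_time = TRUE)
  tgv <- named_prior("tgv")
  temporal <- sum(abs(cupflim:::nth_diff(u, 3L, 2L)))
  expect_equal(composite_prior_value(u, full),
               composite_prior_value(u, tgv) + temporal, tolerance = 1e-12)
})

test_that("prior_config rejects invalid parameters", {
  expect_error(prior_config(p = 0), "p must")
  expect_error(prior_config(p = 1.2), "p must")
  expect_error(prior_config(tau = 2), "tau")
  expect_error(prior_config(order = 3), "order")
  expect_error(prior_config(n_inner = 0), "n_inner")
  # alpha default scales with the stencil: 8 for first-order spatial
  expect_equal(named_prior("tv")$alpha, 8)
  expect_equal(named_prior("3dtv")$alpha, 12)
  expect_equal(named_prior("3dtgpv")$alpha, 48)
})
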