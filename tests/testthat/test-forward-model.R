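test_that("encode multiplies frames by the mask and rejects shape mismatch", {
  cube <- random_cube(3, 3, 2, seed = 1)
  ones <- binary_mask(matrix(1, 3, 3))
  zeros <- binary_mask(matrix(0, 3, 3))
  expect_identical(encode_cube(cube, ones), cube)
  expect_true(all(encode_cube(cube, zeros) == 0))
  expect_error(encode_cube(cube, binary_mask(matrix(1, 4, 3))), "4x3")

  cb <- checkerboard_mask(3, 3)
  A <- diag(rep(as.vector(cb), 2))
  expect_equal(as.vector(encode_cube(cube, cb)), as.vector(A %*% as.vector(cube)))
})

test_that("shear shifts frame t down by t-1 rows onto a padded canvas", {
  cube <- array(0, c(2, 2, 3))
  cube[1, 1, 3] <- 7
  sh <- shear_cube(cube)
  expect_equal(dim(sh), c(4, 2, 3))
  expect_equal(sh[3, 1, 3], 7)       # shifted down by 2 rows
  expect_equal(sum(sh != 0), 1)
  # nt = 1 is the identity
  one <- random_cube(4, 3, 1, seed = 2)
  expect_equal(shear_cube(one), one, ignore_attr = TRUE)
})

test_that("integrate sums over frames; forward_ccd is the named channel", {
  expect_equal(integrate_cube(array(1, c(2, 2, 3))), matrix(3, 2, 2))
  cube <- random_cube(4, 3, 3, seed = 3)
  loop <- matrix(0, 4, 3)
  for (t in 1:3) loop <- loop + cube[, , t]
  expect_equal(integrate_cube(cube), loop)
  expect_equal(forward_ccd(cube), loop)
  expect_equal(integrate_cube(cube[, , 1, drop = FALSE]), cube[, , 1])
})

test_that("forward operators match explicitly assembled dense matrices", {
  for (seed in 1:3) {
    ny <- 4; nx <- 4; nt <- 3
    cube <- random_cube(ny, nx, nt, seed = seed)
    mask <- make_mask(c(ny, nx), 0.5, seed = seed + 50)
    As <- dense_streak_matrix(mask, nt)
    Ac <- dense_ccd_matrix(ny, nx, nt)
    expect_equal(as.vector(forward_streak(cube, mask)),
                 as.vector(As %*% as.vector(cube)), tolerance = 1e-12)
    expect_equal(as.vector(forward_ccd(cube)),
                 as.vector(Ac %*% as.vector(cube)), tolerance = 1e-12)
    # adjoints equal the dense transposes
    y_s <- matrix(rnorm((ny + nt - 1) * nx), ny + nt - 1, nx)
    y_c <- matrix(rnorm(ny * nx), ny, nx)
    expect_equal(as.vector(adjoint_streak(y_s, mask, nt)),
                 as.vector(t(As) %*% as.vector(y_s)), tolerance = 1e-12)
    expect_equal(as.vector(adjoint_ccd(y_c, nt)),
                 as.vector(t(Ac) %*% as.vector(y_c)), tolerance = 1e-12)
    # gram diagonal matches the dense A_s A_s' diagonal
    expect_equal(as.vector(gram_diagonal_streak(mask, nt)),
                 diag(As %*% t(As)), tolerance = 1e-12)
  }
})

test_that("adjoint identity holds for both channels on random instances", {
  set.seed(42)
  for (k in 1:20) {
    ny <- sample(2:6, 1); nx <- sample(2:6, 1); nt <- sample(1:4, 1)
    cube <- array(rnorm(ny * nx * nt), c(ny, nx, nt))
    mask <- make_mask(c(ny, nx), 0.5)
    y_s <- matrix(rnorm((ny + nt - 1) * nx), ny + nt - 1, nx)
    y_c <- matrix(rnorm(ny * nx), ny, nx)
    lhs <- sum(forward_streak(cube, mask) * y_s)
    rhs <- sum(cube * adjoint_streak(y_s, mask, nt))
    expect_lt(abs(lhs - rhs), 1e-10 * max(abs(lhs), 1))
    lhs <- sum(forward_ccd(cube) * y_c)
    rhs <- sum(cube * adjoint_ccd(y_c, nt))
    expect_lt(abs(lhs - rhs), 1e-10 * max(abs(lhs), 1))
  }
  expect_true(all(adjoint_streak(matrix(0, 6, 4), make_mask(c(4, 4), 0.5, seed = 1), 3) == 0))
})

test_that("forward operators are linear and conserve energy", {
  cube1 <- random_cube(5, 4, 3, seed = 7)
  cube2 <- random_cube(5, 4, 3, seed = 8)
  mask <- make_mask(c(5, 4), 0.25, seed = 9)
  lin <- forward_streak(2.5 * cube1 - 1.3 * cube2, mask)
  expect_equal(lin, 2.5 * forward_streak(cube1, mask) - 1.3 * forward_streak(cube2, mask),
               tolerance = 1e-12)
  # shearing and integration move, never destroy, signal
  expect_equal(sum(forward_ccd(cube1)), sum(cube1))
  expect_equal(sum(forward_streak(cube1, mask)), sum(encode_cube(cube1, mask)))
})

test_that("gram diagonal counts overlapping sheared mask rows", {
  ones <- binary_mask(matrix(1, 2, 3))
  gd <- gram_diagonal_streak(ones, 3)
  expect_equal(gd[, 1], c(1, 2, 2, 1))  # direct count of overlapping shifts
  expect_true(all(gram_diagonal_streak(binary_mask(matrix(0, 3, 3)), 2) == 0))
  # gram identity: gd * y == A_s A_s' y
  mask <- make_mask(c(4, 3), 0.5, seed = 10)
  y <- matrix(rnorm(6 * 3), 6, 3)
  expect_equal(gram_diagonal_streak(mask, 3) * y,
               forward_streak(adjoint_streak(y, mask, 3), mask), tolerance = 1e-12)
})

test_that("measurement_pair validates shapes and infers frame count", {
  mp <- measurement_pair(matrix(0, 6, 4), matrix(0, 4, 4))
  expect_equal(mp$nt, 3L)
  expect_error(measurement_pair(matrix(0, 3, 4), matrix(0, 4, 4)), "rows")
  expect_error(measurement_pair(matrix(0, 6, 4), matrix(0, 4, 5)), "column")
})

test_that("cube and mask constructors enforce their invariants", {
  expect_error(video_cube(matrix(0, 2, 2)), "3D")
  expect_error(video_cube(array(NA_real_, c(2, 2, 2))), "finite")
  expect_error(video_cube(array(0, c(2, 2, 2)), dt = 0), "dt")
  expect_error(binary_mask(matrix(0.5, 2, 2)), "0 or 1")
  expect_equal(attr(binary_mask(diag(2)), "transmittance"), 0.5)
})
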