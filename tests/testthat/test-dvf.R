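test_that("zero DVFs are the identity and warp commutes with scaling", {
  grid <- tiny_grid()
  set.seed(3)
  v <- volume(array(runif(16 * 16 * 8), c(16, 16, 8)), grid, "mu")
  w <- warp(v, zero_dvf(grid))
  expect_identical(w$values, v$values)
  d <- smooth_random_dvf(grid, amp = 3, seed = 5)
  w1 <- warp(volume(3 * v$values, grid, "mu"), d)
  w2 <- warp(v, d)
  expect_equal(w1$values, 3 * w2$values, tolerance = 1e-12)
})

test_that("pull convention: +x displacement moves content toward -x", {
  grid <- volume_grid(24, 8, 8, 2)
  v <- array(0, c(24, 8, 8))
  v[12:16, , ] <- 100  # box
  vol <- volume(v, grid, "HU")
  u <- array(0, c(24, 8, 8, 3)); u[, , , 1] <- 6  # +6 mm = 3 voxels
  w <- warp(vol, dvf(u, grid))
  expect_equal(w$values[9:13, 4, 4], rep(100, 5))
  expect_equal(w$values[16, 4, 4], 0)
})

test_that("fractional phase interpolation scales the displacement", {
  grid <- volume_grid(8, 8, 24, 2)
  v <- array(0, c(8, 8, 24)); v[, , 10:14] <- 50
  vol <- volume(v, grid, "HU")
  u <- array(0, c(8, 8, 24, 3)); u[, , , 3] <- 4
  d <- dvf(u, grid)
  expect_identical(interpolate_phase_state(vol, d, 0)$values, vol$values)
  # frac = 0.5 with constant u = (0,0,4): content shifts -2 mm = -1 voxel
  half <- interpolate_phase_state(vol, d, 0.5)
  expect_equal(half$values[4, 4, 9:13], rep(50, 5))
  # frac -> 1 approaches the full warp
  near <- interpolate_phase_state(vol, d, 1 - 1e-9)
  expect_equal(near$values, warp(vol, d)$values, tolerance = 1e-6)
  expect_error(interpolate_phase_state(vol, d, 1), "frac")
  # literal-intensity reading fades intensities (kept for comparison only)
  lit <- interpolate_phase_state(vol, d, 0.5, mode = "intensity")
  expect_equal(max(lit$values), 25)
})

test_that("DVF inversion: closed forms and composition residual", {
  grid <- tiny_grid()
  z <- invert_dvf(zero_dvf(grid))
  expect_true(all(z$u == 0))
  u0 <- array(0, c(16, 16, 8, 3)); u0[, , , 1] <- 3; u0[, , , 3] <- -2
  inv <- invert_dvf(dvf(u0, grid))
  expect_equal(inv$u[, , , 1], array(-3, c(16, 16, 8)), tolerance = 1e-6)
  expect_equal(inv$u[, , , 3], array(2, c(16, 16, 8)), tolerance = 1e-6)
  d <- smooth_random_dvf(grid, amp = 2.5, seed = 9)
  di <- invert_dvf(d, tol = 0.001, max_iter = 100)
  res <- compose_residual(d, di)
  # measure away from the clamped boundary
  core <- array(FALSE, c(16, 16, 8, 3))
  core[4:13, 4:13, 3:6, ] <- TRUE
  expect_lt(max(abs(res[core])), 0.05)
})

test_that("round-trip warp with the numerical inverse restores the volume", {
  ph <- thorax_fixture()
  grid <- ph$grid
  d <- dvf_between(ph, 1, 4)
  di <- invert_dvf(d, tol = 0.001, max_iter = 100)
  v <- ph$phases[[1]]
  rt <- warp(warp(v, d), di)
  rng <- diff(range(v$values))
  expect_lt(mean(abs(rt$values - v$values)) / rng, 0.02)
})

test_that("toy scaling law matches its printed form and bounds", {
  expect_equal(toy_transform(0)$s_xy, 1.0)
  i <- round(pi / 2 / 0.15)  # sin(0.15 i) ~ 1
  expect_equal(toy_transform(i)$s_xy, 1 + 0.1 * sin(0.15 * i))
  expect_equal(toy_transform(i)$s_xy, 1.1, tolerance = 1e-3)
  s <- vapply(0:657, function(i) toy_transform(i)$s_xy, 0)
  expect_true(all(s >= 0.9 & s <= 1.1))
  expect_error(toy_transform(1, amplitude = 1), "non-invertible")
  expect_error(affine_scaling(-1), "positive")
})

test_that("scaling DVFs follow the closed form and the warp identity", {
  grid <- volume_grid(32, 32, 8, 3)
  s11 <- affine_scaling(1.1)
  s10 <- affine_scaling(1.0)
  expect_true(all(scaling_dvf(s11, s11, grid)$u == 0))
  d <- scaling_dvf(s11, s10, grid)
  co <- grid_coords(grid)
  ix <- which.min(abs(co$x - 45))
  iy <- which.min(abs(co$y))
  # u = (s_src/s_tgt - 1) * (x, y, 0)
  expect_equal(d$u[ix, iy, 4, 1], 0.1 * co$x[ix], tolerance = 1e-9)
  expect_equal(d$u[ix, iy, 4, 3], 0)
  # warping the src-scaled toy state yields the tgt state (object kept
  # well inside the grid so boundary clamping plays no role)
  ins <- list(list(type = "disc", center = c(15, 0), radius = 6),
              list(type = "disc", center = c(-12, 10), radius = 5),
              list(type = "bar", center = c(0, -15), half_size = c(10, 3)))
  v_src <- make_toy_phantom(grid, ins, scale = 1.1, radius = 35)
  v_tgt <- make_toy_phantom(grid, ins, scale = 1.0, radius = 35)
  w <- warp(v_src, d)
  expect_lt(mean(abs(w$values - v_tgt$values)) / 2000, 0.01)
})

test_that("DVFs round-trip through 4D NIfTI", {
  grid <- tiny_grid()
  d <- smooth_random_dvf(grid, amp = 2, seed = 2)
  d$source <- 1; d$target <- 5
  path <- tempfile(fileext = ".nii.gz")
  write_dvf(d, path)
  d2 <- read_dvf(path)
  expect_equal(d2$u, d$u, tolerance = 1e-6)
  expect_equal(d2$source, 1)
  expect_equal(d2$grid$voxel_size, 4)
})
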