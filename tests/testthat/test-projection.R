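test_that("forward projection is linear and zero on zero volumes", {
  grid <- tiny_grid()
  geom <- tiny_geom(3)
  zero <- volume(array(0, c(16, 16, 8)), grid, "mu")
  expect_true(all(forward_project(zero, geom)$frames == 0))
  set.seed(4)
  a <- volume(array(runif(16 * 16 * 8), c(16, 16, 8)), grid, "mu")
  b <- volume(array(runif(16 * 16 * 8), c(16, 16, 8)), grid, "mu")
  pa <- forward_project(a, geom)$frames
  pb <- forward_project(b, geom)$frames
  ab <- volume(2 * a$values + 3 * b$values, grid, "mu")
  expect_equal(forward_project(ab, geom)$frames, 2 * pa + 3 * pb,
               tolerance = 1e-12)
  expect_error(forward_project(a, geom, view_indices = 99), "out of range")
  expect_error(volume(array(NaN, c(16, 16, 8)), grid, "mu"), "finite")
})

test_that("central ray through a water cylinder integrates to the chord", {
  fx <- cyl_fixture()
  geom <- tiny_geom(2)
  p <- forward_project(fx$vol, geom, 1, step = 0.5)
  iu <- round((0 - geom$detector_offset_u) / geom$pixel_u +
                (geom$n_u - 1) / 2) + 1
  iv <- round((geom$n_v - 1) / 2) + 1
  # mu * diameter = 0.02 * 120 = 2.4; voxelized edge gives a few percent
  expect_equal(p$frames[iu, iv, 1], 0.02 * 120, tolerance = 0.05)
})

test_that("isocenter features magnify by sdd/sid on the detector", {
  grid <- volume_grid(32, 32, 8, 2)
  # fine detector pixels so the projected footprint spans several rows
  geom <- cone_beam_geometry(1000, 1500, 96, 32, 1, 5,
                             detector_offset_u = 10, n_views = 1)
  co <- grid_coords(grid)
  pt <- array(0, c(32, 32, 8))
  iy <- which.min(abs(co$y - 10))
  ix <- which.min(abs(co$x))
  pt[ix, iy, which.min(abs(co$z))] <- 1
  p <- forward_project(volume(pt, grid, "mu"), geom, 1, step = 0.5)
  um <- ((seq_len(geom$n_u) - 1) - (geom$n_u - 1) / 2) * geom$pixel_u +
    geom$detector_offset_u
  centroid <- sum(p$frames[, , 1] %*% rep(1, geom$n_v) * um) / sum(p$frames)
  # angle 0: e_u = (0, 1, 0); magnification at depth x is sdd/(sid - x)
  expect_equal(centroid, co$y[iy] * geom$sdd / (geom$sid - co$x[ix]),
               tolerance = 0.02)
})

test_that("unfiltered backprojection is the adjoint of forward projection", {
  grid <- tiny_grid()
  geom <- tiny_geom(4)
  set.seed(7)
  v <- volume(array(runif(16 * 16 * 8), c(16, 16, 8)), grid, "mu")
  p <- forward_project(v, geom, step = 2)
  q <- array(runif(length(p$frames)), dim(p$frames))
  lhs <- sum(p$frames * q)
  xt <- Reduce(`+`, lapply(1:4, function(i)
    backproject_single_unfiltered(projection_set(q, geom), i, grid,
                                  step = 2)$values))
  rhs <- sum(xt * v$values)
  expect_equal(lhs, rhs, tolerance = 0.01)
  # uniform frames give strictly positive values inside the cone
  ones <- projection_set(array(1, dim(p$frames)), geom)
  bp <- backproject_single_unfiltered(ones, 1, grid, step = 2)
  expect_gt(bp$values[8, 8, 4], 0)
  # zero frame gives a zero volume
  zf <- projection_set(array(0, dim(p$frames)), geom)
  expect_true(all(backproject_single_unfiltered(zf, 1, grid)$values == 0))
})

test_that("FDK recovers the attenuation of a static cylinder", {
  fx <- cyl_fixture()
  geom <- cone_beam_geometry(1000, 1500, 96, 32, 3, 5,
                             detector_offset_u = 30, n_views = 96)
  p <- forward_project(fx$vol, geom, step = 2)
  rec <- fdk_reconstruct(p, fx$grid)
  co <- grid_coords(fx$grid)
  interior <- array(sqrt(outer(co$x^2, co$y^2, "+")) < 40, c(48, 48, 16))
  interior[, , c(1:4, 13:16)] <- FALSE
  expect_equal(mean(rec$values[interior]), 0.02, tolerance = 0.03)
  # zero projections reconstruct to zero
  z <- projection_set(array(0, dim(p$frames)), geom)
  expect_true(all(fdk_reconstruct(z, fx$grid)$values == 0))
})

test_that("summing all single-angle reconstructions reproduces FDK exactly", {
  fx <- cyl_fixture()
  geom <- tiny_geom(8)
  p <- forward_project(fx$vol, geom, step = 2)
  rec <- fdk_reconstruct(p, fx$grid)
  s <- Reduce(`+`, lapply(1:8, function(i)
    backproject_single_filtered(p, i, fx$grid)$values))
  expect_equal(s, rec$values, tolerance = 1e-12)
  # single SAR of a zero frame is zero
  z <- projection_set(array(0, dim(p$frames)), geom)
  expect_true(all(backproject_single_filtered(z, 1, fx$grid)$values == 0))
})

test_that("a shifted-detector scan matches a centered scan of doubled width", {
  fx <- cyl_fixture()
  shifted <- cone_beam_geometry(1000, 1500, 80, 32, 3, 5,
                                detector_offset_u = 54, n_views = 80)
  centered <- cone_beam_geometry(1000, 1500, 160, 32, 3, 5,
                                 detector_offset_u = 0, n_views = 80)
  r1 <- fdk_reconstruct(forward_project(fx$vol, shifted, step = 2), fx$grid)
  r2 <- fdk_reconstruct(forward_project(fx$vol, centered, step = 2), fx$grid)
  co <- grid_coords(fx$grid)
  m <- array(sqrt(outer(co$x^2, co$y^2, "+")) < 55, c(48, 48, 16))
  m[, , c(1:4, 13:16)] <- FALSE
  expect_lt(mean(abs(r1$values[m] - r2$values[m])), 0.0012)  # ~6% of water
})

test_that("short-arc shifted-detector scans are rejected", {
  fx <- cyl_fixture()
  geom <- cone_beam_geometry(1000, 1500, 48, 32, 5, 5,
                             detector_offset_u = 20,
                             angles = seq(0, pi, length.out = 20))
  p <- projection_set(array(0, c(48, 32, 20)), geom)
  expect_error(fdk_reconstruct(p, fx$grid), "full rotation")
})
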