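test_that("toy phantom renders the cylinder and its inserts", {
  grid <- volume_grid(48, 48, 8, 3)
  plain <- make_toy_phantom(grid, inserts = list(), radius = 60)
  co <- grid_coords(grid)
  ic <- which.min(abs(co$x))
  expect_equal(plain$values[ic, ic, 4], 0)           # water center
  expect_equal(plain$values[1, 1, 4], -1000)         # air corner
  ph <- make_toy_phantom(grid, radius = 60)
  ins <- toy_inserts()[[1]]
  ix <- which.min(abs(co$x - ins$center[1]))
  iy <- which.min(abs(co$y - ins$center[2]))
  expect_equal(ph$values[ix, iy, 4], 1000)           # insert center
  # insert voxel count ~ analytic area x slices
  n_ins <- sum(ph$values[, , 4] > 500)
  area <- sum(vapply(toy_inserts(), function(i)
    if (i$type == "disc") pi * i$radius^2 else 4 * prod(i$half_size), 0))
  expect_equal(n_ins * grid$voxel_size^2, area, tolerance = 0.2)
  expect_error(make_toy_phantom(grid, inserts = list(
    list(type = "disc", center = c(55, 20), radius = 10)), radius = 60),
    "outside")
})

test_that("zero excursion freezes all phases and DVFs", {
  grid <- volume_grid(24, 24, 16, 6)
  ph <- make_thorax_phantom(grid, thorax_params(excursion = 0, seed = 2),
                            seed = 2)
  for (i in 2:10) {
    expect_identical(ph$phases[[i]]$values, ph$phases[[1]]$values)
    expect_identical(ph$labels[[i]], ph$labels[[1]])
  }
  expect_true(all(dvf_between(ph, 1, 6)$u == 0))
})

test_that("exact DVFs satisfy the warp identity across phases", {
  ph <- thorax_fixture()
  w <- warp(ph$phases[[1]], dvf_between(ph, 1, 6))
  contrast <- 840  # lung to soft tissue
  expect_lt(mean(abs(w$values - ph$phases[[6]]$values)) / contrast, 0.02)
  # and for a non-adjacent reverse pair
  w2 <- warp(ph$phases[[8]], dvf_between(ph, 8, 3))
  expect_lt(mean(abs(w2$values - ph$phases[[3]]$values)) / contrast, 0.02)
})

test_that("diaphragm moves much more than the ribs", {
  ph <- thorax_fixture()
  d <- dvf_between(ph, 1, 6)  # end-exhale -> end-inhale
  mag <- sqrt(d$u[, , , 1]^2 + d$u[, , , 2]^2 + d$u[, , , 3]^2)
  lab <- ph$labels[[1]]
  expect_gt(mean(mag[lab == 5L]), mean(mag[lab == 4L]))
  expect_gt(mean(mag[lab == 5L]), 3 * mean(mag[lab == 4L]))
})

test_that("phantom generation is reproducible and labels persist", {
  grid <- volume_grid(24, 24, 16, 6)
  a <- make_thorax_phantom(grid, thorax_params(excursion = 12, seed = 5),
                           seed = 5)
  b <- make_thorax_phantom(grid, thorax_params(excursion = 12, seed = 5),
                           seed = 5)
  expect_identical(a$phases[[3]]$values, b$phases[[3]]$values)
  expect_identical(a$labels[[7]], b$labels[[7]])
  # no anatomical class vanishes in any phase, counts change smoothly
  counts <- sapply(a$labels, function(l) tabulate(l + 1L, 7L))
  expect_true(all(counts[2:7, ] > 0))
  rel <- apply(counts, 1, function(x) max(abs(diff(x))) / max(x))
  expect_true(all(rel < 0.35))
})

test_that("folding excursions are rejected", {
  grid <- volume_grid(24, 24, 16, 6)
  expect_error(thorax_params(excursion = 90), "range")
  p <- thorax_params(excursion = 38, seed = 1)
  p$psi_zbase <- -10; p$psi_zapex <- 10  # steep decay: |a g psi'| > 1
  expect_error(make_thorax_phantom(grid, p), "fold")
})

test_that("fractional states interpolate between integer phases", {
  ph <- thorax_fixture()
  expect_identical(phantom_state(ph, 1)$values, ph$phases[[1]]$values)
  mid <- phantom_state(ph, 3.5)
  a <- amplitude_of(ph, 3.5)
  expect_equal(a, (ph$amplitudes[3] + ph$amplitudes[4]) / 2)
  d <- mean(abs(mid$values - ph$phases[[3]]$values))
  d2 <- mean(abs(ph$phases[[4]]$values - ph$phases[[3]]$values))
  expect_lt(d, d2)  # closer than a full phase step
  # wrap-around: phase 10.5 lies between phase 10 and phase 1
  a105 <- amplitude_of(ph, 10.5)
  expect_equal(a105, (ph$amplitudes[10] + ph$amplitudes[1]) / 2)
  expect_error(amplitude_of(ph, 11), "\\[1, 11\\)")
})
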