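test_that("full-window gating equals the plain FDK reconstruction", {
  scan <- thorax_scan_fixture()
  grid <- scan$phantom$grid
  full <- gated_reconstruct(scan, gating_window(3, width_fraction = 1), grid)
  fdk <- fdk_reconstruct(scan$projections, grid)
  expect_equal(full$values, fdk$values, tolerance = 1e-12)
})

test_that("a 20% window on a periodic signal selects about a fifth of views", {
  # incommensurate cycle count so phases do not sit exactly on the
  # window boundary lattice
  sig <- periodic_signal(400, cycles = 7)
  sel <- gated_views(sig, gating_window(6, 0.20))
  expect_gt(length(sel), 0.9 * 400 / 5)
  expect_lt(length(sel), 1.1 * 400 / 5)
  # gating distance is cyclic: a window centered near phase 1 wraps
  selw <- gated_views(phase_signal(c(1.2, 10.8, 5.5)), gating_window(1, 0.2))
  expect_equal(selw, c(1L, 2L))
})

test_that("an unvisited phase raises an empty-bin error naming the phase", {
  scan <- thorax_scan_fixture()
  sig <- phase_signal(rep(2, scan$geometry$n_views))
  scan2 <- scan
  scan2$signal <- sig
  expect_error(gated_reconstruct(scan2, gating_window(7, 0.1),
                                 scan$phantom$grid), "empty.*7")
})

test_that("modified SAR is a fixed point on consistent static data", {
  fx <- cyl_fixture()
  geom <- tiny_geom(4)
  p <- forward_project(fx$vol, geom, step = 2)
  fbar <- fx$vol  # consistent: p == X fbar by construction
  scanlike <- list(projections = p)
  g1 <- modified_sar(scanlike, 2, fbar, step = 2)
  expect_equal(g1$values, fbar$values, tolerance = 1e-10)
  # zero data and zero fbar stay zero
  z <- list(projections = projection_set(array(0, dim(p$frames)), geom))
  zf <- volume(array(0, dim(fx$vol$values)), fx$grid, "mu")
  expect_true(all(modified_sar(z, 1, zf, step = 2)$values == 0))
  expect_error(modified_sar(scanlike, 1, fbar, eps = 0), "positive")
})

test_that("modified SAR pulls a displaced sphere toward its view-i position", {
  grid <- volume_grid(32, 32, 8, 4)
  geom <- cone_beam_geometry(1000, 1500, 64, 24, 4, 6,
                             detector_offset_u = 30, n_views = 16)
  co <- grid_coords(grid)
  mk_sphere <- function(cx) {
    v <- array(0, c(32, 32, 8))
    d2 <- outer((co$x - cx)^2, co$y^2, "+")
    v[] <- ifelse(sqrt(d2) < 20, 0.02, 0)
    volume(v, grid, "mu")
  }
  # half the scan sees the sphere at x=-16, half at x=+16
  pa <- forward_project(mk_sphere(-16), geom, 1:8, step = 2)$frames
  pb <- forward_project(mk_sphere(16), geom, 9:16, step = 2)$frames
  p <- projection_set(array(c(pa, pb), c(64, 24, 16)), geom)
  fbar <- fdk_reconstruct(p, grid)
  scanlike <- list(projections = p)
  centroid_x <- function(v) sum(v$values * co$x) / sum(v$values)
  g_late <- modified_sar(scanlike, 12, fbar, step = 2)
  expect_gt(centroid_x(g_late), centroid_x(fbar) + 1)
})

test_that("SAMoCo with zero DVFs reduces to FDK and caches SARs", {
  scan <- thorax_scan_fixture()
  grid <- scan$phantom$grid
  fdk <- fdk_reconstruct(scan$projections, grid)
  rec <- samoco_reconstruct(scan, dvf_provider_zero(grid), 5, grid)
  expect_equal(rec$values, fdk$values, tolerance = 1e-12)
  cache <- tempfile("sars_")
  s1 <- compute_sars(scan, grid, cache_dir = cache)
  expect_true(file.exists(file.path(cache, "sar_00001.rds")))
  s2 <- compute_sars(scan, grid, cache_dir = cache)
  expect_identical(s1[[3]]$values, s2[[3]]$values)
})

test_that("provider failures name the offending pair", {
  scan <- thorax_scan_fixture()
  grid <- scan$phantom$grid
  bad <- structure(function(i, n) stop("boom"),
                   class = c("dvf_provider", "function"))
  sars <- compute_sars(scan, grid)
  expect_error(samoco_reconstruct(scan, bad, 2, grid, sars = sars),
               "pair \\(1, 2\\)")
})

test_that("oracle SAMoCo beats uncorrected FDK on a moving phantom", {
  scan <- thorax_scan_fixture()
  grid <- scan$phantom$grid
  ref <- 1
  gt <- scan_gt_volume(scan, ref, with_labels = TRUE)
  msk <- body_mask(gt$labels)
  fdk <- fdk_reconstruct(scan$projections, grid)
  sam <- samoco_reconstruct(scan, dvf_provider_oracle(scan, grid), ref, grid)
  expect_lt(mae_hu(sam, gt$volume, msk), mae_hu(fdk, gt$volume, msk))
})

test_that("4D SAMoCo maps over references and is static-consistent", {
  ph <- thorax_fixture()
  geom <- thorax_geom(12)
  static <- simulate_scan(ph, phase_signal(rep(2, 12)), geom)
  grid <- ph$grid
  prov <- dvf_provider_oracle(static, grid)
  recs <- samoco_4d(static, prov, c(1, 5, 9), grid)
  expect_length(recs, 3)
  expect_equal(recs[[1]]$values, recs[[3]]$values, tolerance = 1e-10)
  single <- samoco_reconstruct(static, prov, 5, grid)
  expect_equal(recs[[2]]$values, single$values, tolerance = 1e-12)
})

test_that("4D toy reconstruction tracks the per-view scaling law", {
  grid <- volume_grid(48, 48, 8, 4)
  geom <- cone_beam_geometry(1000, 1500, 120, 60, 2.6, 4,
                             detector_offset_u = 50, n_views = 120)
  ts <- simulate_toy_scan(grid, geom, amplitude = 0.1, freq = 0.15,
                          radius = 55, edge_mm = 4)
  refs <- round(seq(1, 120, length.out = 10))
  recs <- samoco_4d(ts, dvf_provider_toy(ts$scales, grid), refs, grid,
                    window = "ramlak")
  # measured in-plane scale: sqrt of the cylinder cross-section area
  mid <- 4
  area <- vapply(recs, function(r)
    sum(mu_to_hu(r$values[, , mid]) > -500), 0)
  measured <- sqrt(area / area[1]) * ts$scales[refs[1]]
  expect_gt(cor(measured, ts$scales[refs]), 0.95)
})
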