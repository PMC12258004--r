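test_that("a constant-phase signal reproduces a static scan", {
  ph <- thorax_fixture()
  geom <- thorax_geom(6)
  scan <- simulate_scan(ph, phase_signal(rep(4, 6)), geom)
  static_mu <- convert_unit(ph$phases[[4]], "mu")
  p_static <- forward_project(static_mu, geom)
  expect_equal(scan$projections$frames, p_static$frames, tolerance = 1e-12)
  expect_equal(dim(scan$projections$frames)[3], 6L)
})

test_that("scan oracles satisfy the warp identity on view pairs", {
  scan <- thorax_scan_fixture()
  contrast <- 840
  for (pair in list(c(3, 20), c(10, 41))) {
    gi <- scan_gt_volume(scan, pair[1])
    gn <- scan_gt_volume(scan, pair[2])
    w <- warp(gi, scan_gt_dvf(scan, pair[1], pair[2]))
    expect_lt(mean(abs(w$values - gn$values)) / contrast, 0.02)
  }
})

test_that("Poisson noise is seeded and leaves projections non-negative", {
  ph <- thorax_fixture()
  geom <- thorax_geom(3)
  s1 <- simulate_scan(ph, phase_signal(rep(1, 3)), geom,
                      noise_photons = 5e4, seed = 3)
  s2 <- simulate_scan(ph, phase_signal(rep(1, 3)), geom,
                      noise_photons = 5e4, seed = 3)
  expect_identical(s1$projections$frames, s2$projections$frames)
  clean <- simulate_scan(ph, phase_signal(rep(1, 3)), geom)
  expect_false(identical(s1$projections$frames, clean$projections$frames))
  # noise perturbs but does not bias the line integrals appreciably
  expect_lt(abs(mean(s1$projections$frames - clean$projections$frames)),
            0.01)
})

test_that("toy scans apply the printed per-view scaling law", {
  grid <- volume_grid(24, 24, 8, 4)
  geom <- tiny_geom(5)
  ts <- simulate_toy_scan(grid, geom, amplitude = 0.1, freq = 0.15)
  expect_equal(ts$scales, 1 + 0.1 * sin(0.15 * (0:4)))
  # amplitude 0: every view equals the static phantom projection
  ts0 <- simulate_toy_scan(grid, geom, amplitude = 0)
  static <- forward_project(convert_unit(make_toy_phantom(grid), "mu"), geom)
  expect_equal(ts0$projections$frames, static$frames, tolerance = 1e-12)
})

test_that("scan records persist to a plain-file directory", {
  scan <- thorax_scan_fixture()
  dir <- tempfile("scanrec_")
  write_scan_record(scan, dir)
  expect_true(all(file.exists(file.path(dir,
    c("projections.nii.gz", "geometry.json", "signal.csv", "phantom.yaml",
      "labels_legend.json", "labels_phase1.nii.gz")))))
  rec <- read_scan_record(dir)
  expect_equal(rec$projections$frames, scan$projections$frames,
               tolerance = 1e-6)
  expect_equal(rec$signal$phi, scan$signal$phi, tolerance = 1e-12)
  expect_equal(rec$params$excursion, scan$phantom$params$excursion)
})
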