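# Shared fixtures, built once per test run and memoised. All sizes are
# deliberately small so the whole suite stays fast; the acceptance tests
# use their own (larger) fixture.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

tiny_grid <- function() volume_grid(16, 16, 8, 4)

tiny_geom <- function(n_views = 6) {
  cone_beam_geometry(sid = 1000, sdd = 1500, n_u = 48, n_v = 32,
                     pixel_u = 5, pixel_v = 5, detector_offset_u = 20,
                     n_views = n_views)
}

# small water cylinder (attenuation units) on its own grid
cyl_fixture <- function() memo("cyl", {
  grid <- volume_grid(48, 48, 16, 4)
  co <- grid_coords(grid)
  v <- array(0, c(48, 48, 16))
  v[] <- ifelse(sqrt(outer(co$x^2, co$y^2, "+")) <= 60, 0.02, 0)
  list(grid = grid, vol = volume(v, grid, "mu"))
})

# small thorax phantom covering the full anatomy at 5 mm voxels
thorax_fixture <- function() memo("thorax", {
  grid <- volume_grid(40, 40, 28, 5)
  make_thorax_phantom(grid, thorax_params(excursion = 15, seed = 11),
                      seed = 11)
})

# modest geometry matched to the thorax fixture
thorax_geom <- function(n_views = 48) {
  cone_beam_geometry(sid = 1000, sdd = 1500, n_u = 96, n_v = 72,
                     pixel_u = 3.6, pixel_v = 3.6, detector_offset_u = 40,
                     n_views = n_views)
}

# a simulated breathing scan of the thorax fixture
thorax_scan_fixture <- function() memo("thorax_scan", {
  ph <- thorax_fixture()
  sig <- periodic_signal(48, cycles = 4)
  simulate_scan(ph, sig, thorax_geom(48))
})

# smooth random DVF for inversion / warp property tests
smooth_random_dvf <- function(grid, amp = 4, seed = 1) {
  set.seed(seed)
  co <- grid_coords(grid)
  u <- array(0, c(grid$nx, grid$ny, grid$nz, 3L))
  for (c_ in 1:3) {
    ph <- runif(3, 0, 2 * pi)
    fx <- sin(2 * pi * co$x / diff(range(co$x)) / 1.5 + ph[1])
    fy <- cos(2 * pi * co$y / diff(range(co$y)) / 1.5 + ph[2])
    fz <- sin(2 * pi * co$z / diff(range(co$z)) / 1.2 + ph[3])
    u[, , , c_] <- amp * outer(outer(fx, fy), fz)
  }
  dvf(u, grid)
}
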