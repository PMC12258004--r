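test_that("sigmoid fits recover noiseless generative parameters exactly", {
  z <- seq(20, 60, by = 0.5)
  y <- 1000 / (1 + exp(-1 * (z - 40))) + (-1000)
  ft <- fit_sigmoid_profile(z, y)
  expect_true(ft$converged)
  expect_equal(ft$z0, 40, tolerance = 1e-3)
  expect_equal(ft$h, 1000, tolerance = 1e-2)
  expect_equal(ft$c, 1, tolerance = 1e-4)
  expect_equal(ft$b, -1000, tolerance = 1e-2)
})

test_that("sigmoid fits are unbiased under symmetric noise", {
  z <- seq(20, 60, by = 0.5)
  clean <- 1000 / (1 + exp(-1 * (z - 40))) - 1000
  set.seed(42)
  err <- replicate(100, {
    ft <- fit_sigmoid_profile(z, clean + rnorm(length(z), sd = 20))
    ft$z0 - 40
  })
  expect_lt(abs(mean(err)), 0.5)
})

test_that("degenerate profiles are flagged, not raised", {
  z <- seq(0, 20, by = 1)
  flat <- fit_sigmoid_profile(z, rep(5, length(z)))
  expect_false(flat$converged)
  expect_error(fit_sigmoid_profile(1:5, 1:5), "at least 8")
  # falling edges fit too (negative h)
  y <- -800 / (1 + exp(-0.8 * (z - 10))) + 40
  ft <- fit_sigmoid_profile(z, y)
  expect_true(ft$converged)
  expect_equal(ft$z0, 10, tolerance = 1e-2)
})

test_that("diaphragm estimates are deterministic and track excursion", {
  ph <- thorax_fixture()
  a <- diaphragm_position(ph$phases[[1]], ph$labels[[1]], n_profiles = 80,
                          seed = 2)
  b <- diaphragm_position(ph$phases[[1]], ph$labels[[1]], n_profiles = 80,
                          seed = 2)
  expect_identical(a$position, b$position)
  expect_false(a$flagged)
  # end-inhale sits inferior (more negative z) to end-exhale
  c6 <- diaphragm_position(ph$phases[[6]], ph$labels[[6]], n_profiles = 80,
                           seed = 2)
  expect_gt(a$position - c6$position, 0.5 * ph$params$excursion)
  expect_lt(a$position - c6$position, 1.1 * ph$params$excursion)
})

test_that("DVF class statistics match a brute-force nested-loop oracle", {
  set.seed(8)
  grid <- volume_grid(8, 8, 4, 2)
  n_entries <- 4  # e.g. 2 phases x 2 angle draws
  pred <- list(); gt <- list(); labs <- list()
  for (k in seq_len(n_entries)) {
    pred[[k]] <- dvf(array(rnorm(8 * 8 * 4 * 3), c(8, 8, 4, 3)), grid)
    gt[[k]] <- dvf(array(rnorm(8 * 8 * 4 * 3), c(8, 8, 4, 3)), grid)
    labs[[k]] <- array(sample(0:6, 8 * 8 * 4, replace = TRUE), c(8, 8, 4))
  }
  st <- dvf_class_stats(pred, gt, labs)
  # independent brute-force summation, scalar loops
  for (cl in st$class) {
    code <- c(lung = 1, lung_nodule = 2, heart = 3, ribs = 4,
              diaphragm = 5, remainder = 6)[[cl]]
    s_p <- 0; s_e <- 0; K <- 0
    for (k in seq_len(n_entries)) {
      for (i in 1:8) for (j in 1:8) for (l in 1:4) {
        if (labs[[k]][i, j, l] == code) {
          up <- pred[[k]]$u[i, j, l, ]; ug <- gt[[k]]$u[i, j, l, ]
          s_p <- s_p + sqrt(sum(up^2))
          s_e <- s_e + sqrt(sum((up - ug)^2))
          K <- K + 1
        }
      }
    }
    row <- st[st$class == cl, ]
    expect_equal(row$mean_pred, s_p / K, tolerance = 1e-12)
    expect_equal(row$mae, s_e / K, tolerance = 1e-12)
    expect_equal(row$n_voxels, K)
  }
})

test_that("DVF class statistics handle trivial and degenerate inputs", {
  grid <- volume_grid(6, 6, 4, 3)
  u <- array(0, c(6, 6, 4, 3)); u[, , , 1] <- 1
  lab <- array(rep(c(1L, 6L), each = 72), c(6, 6, 4))
  st <- dvf_class_stats(list(dvf(u, grid)), list(zero_dvf(grid)), list(lab))
  expect_equal(st$mean_pred, c(1, 1))
  expect_equal(st$mae, c(1, 1))
  # pred == gt gives zero error
  st2 <- dvf_class_stats(list(dvf(u, grid)), list(dvf(u, grid)), list(lab))
  expect_equal(st2$mae, c(0, 0))
  expect_message(dvf_class_stats(list(zero_dvf(grid)), list(zero_dvf(grid)),
                                 list(array(1L, c(6, 6, 4)))), "omitted")
})

test_that("HU error metric agrees with direct summation", {
  grid <- volume_grid(6, 6, 4, 3)
  set.seed(2)
  a <- volume(array(rnorm(144, sd = 50), c(6, 6, 4)), grid, "HU")
  expect_equal(mae_hu(a, a), 0)
  b <- volume(a$values + 10, grid, "HU")
  expect_equal(mae_hu(b, a, array(TRUE, c(6, 6, 4))), 10)
  c_ <- volume(array(rnorm(144, sd = 50), c(6, 6, 4)), grid, "HU")
  m <- array(rep(c(TRUE, FALSE), 72), c(6, 6, 4))
  expect_equal(mae_hu(c_, a, m), mean(abs(c_$values[m] - a$values[m])))
  expect_error(mae_hu(a, volume(array(0, c(4, 4, 2)),
                                volume_grid(4, 4, 2, 3), "HU")), "differ")
})

test_that("evaluation reports write reloadable curves and metrics", {
  scan <- thorax_scan_fixture()
  grid <- scan$phantom$grid
  refs <- c(1, 25)
  sams <- samoco_4d(scan, dvf_provider_oracle(scan, grid), refs, grid)
  out <- tempfile("report_")
  met <- evaluation_report(scan, list(samoco = sams), refs, out,
                           n_profiles = 60, seed = 4)
  curves <- read.csv(file.path(out, "diaphragm_curves.csv"))
  expect_equal(nrow(curves), length(refs))
  expect_true(all(c("ground_truth", "samoco") %in% names(curves)))
  expect_true(file.exists(file.path(out, "metrics.json")))
  expect_equal(met$method, "samoco")
  expect_lt(met$diaphragm_mad_mm, 3)
  # empty reconstruction set: header-only outputs
  met0 <- evaluation_report(scan, list(), refs, tempfile(),
                            n_profiles = 40, seed = 4)
  expect_equal(nrow(met0), 0)
})
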