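test_that("training pairs carry the exact phantom DVF as label", {
  ph <- thorax_fixture()
  geom <- thorax_geom(10)
  ctx <- phantom_train_context(ph, geom, seed = 3)
  set.seed(21)
  pr <- sample_training_pair(ctx)
  expect_identical(pr$label$u,
                   dvf_between(ph, pr$phase_i, pr$phase_n)$u)
  # same RNG state reproduces the sample
  set.seed(21)
  pr2 <- sample_training_pair(ctx)
  expect_identical(pr2$g_i$values, pr$g_i$values)
  expect_equal(pr2$angle_i, pr$angle_i)
  # identical phases give the zero-DVF label
  set.seed(1)
  repeat {
    p3 <- sample_training_pair(ctx)
    if (p3$phase_i == p3$phase_n) break
  }
  expect_lt(max(abs(p3$label$u)), 1e-6)  # Newton-solve tolerance
})

test_that("DVF training drives the loss down and is seed-deterministic", {
  ph <- thorax_fixture()
  geom <- thorax_geom(10)
  ctx <- list(phantom_train_context(ph, geom, seed = 3))
  # tiny network on the fixture grid (40 x 40 x 28 divisible by 4)
  m0 <- build_dvfnet(unet_config(2, 2, 2, 3), seed = 1)
  cfg <- train_config(lr = 2e-3, batch = 2, epochs = 3,
                      samples_per_phantom = 4, seed = 7)
  m1 <- train_dvfnet(m0, ctx, ctx, cfg, n_val = 2)
  expect_equal(nrow(m1$history), 3)
  expect_lt(m1$history$train_loss[3], m1$history$train_loss[1])
  m2 <- train_dvfnet(m0, ctx, ctx, cfg, n_val = 2)
  expect_identical(m1$history$val_loss, m2$history$val_loss)
  expect_identical(m1$params, m2$params)
  expect_error(train_dvfnet(m0, list(), ctx, cfg), "non-empty")
})

test_that("a network overfits one fixed pair far below its initial loss", {
  ph <- thorax_fixture()
  geom <- thorax_geom(10)
  ctx <- phantom_train_context(ph, geom, seed = 3)
  set.seed(5)
  pr <- sample_training_pair(ctx)
  cfg <- unet_config(2, 4, 2, 3)
  m <- build_dvfnet(cfg, seed = 2)
  x <- samoco4d:::dvfnet_input(pr$g_i, pr$g_n)
  y <- pr$label$u / ph$grid$voxel_size
  p <- m$params; st <- NULL
  l0 <- samoco4d:::.cpp_unet_loss_grad(p, x, y, unclass(cfg))$loss
  for (k in 1:80) {
    lg <- samoco4d:::.cpp_unet_loss_grad(p, x, y, unclass(cfg))
    ad <- samoco4d:::adam_step(p, lg$grad, st, 5e-3)
    p <- ad$params; st <- ad$state
  }
  expect_lt(lg$loss, 0.01 * l0)
})

test_that("RAC examples pair SAMoCo inputs with ideal-MoCo labels", {
  ph <- thorax_fixture()
  geom <- thorax_geom(10)
  set.seed(9)
  ex <- make_rac_example(ph, geom)
  expect_true(all(ex$phases %in% 1:10))
  # the label IS the static-scan FDK of the reference state
  ref_ph <- ex$phases[ex$ref_view]
  static <- simulate_scan(ph, phase_signal(rep(ref_ph, geom$n_views)), geom)
  lab2 <- convert_unit(fdk_reconstruct(static$projections, ph$grid), "HU")
  expect_equal(ex$label$values, lab2$values, tolerance = 1e-10)
  # seeded reproducibility
  set.seed(9)
  ex2 <- make_rac_example(ph, geom)
  expect_identical(ex2$input$values, ex$input$values)
})

test_that("a static phantom yields RAC examples with vanishing artifact", {
  grid <- volume_grid(24, 24, 16, 6)
  ph0 <- make_thorax_phantom(grid, thorax_params(excursion = 0, seed = 2),
                             seed = 2)
  geom <- thorax_geom(8)
  set.seed(1)
  ex <- make_rac_example(ph0, geom)
  expect_lt(mean(abs(ex$input$values - ex$label$values)), 1e-8)
})

test_that("RAC training reduces validation loss on held-out sequences", {
  grid <- volume_grid(24, 24, 16, 6)
  mk <- function(s) make_thorax_phantom(
    grid, thorax_params(excursion = 12, seed = s), seed = s)
  geom <- thorax_geom(12)
  m0 <- build_racnet(unet_config(2, 4, 1, 1), seed = 1)
  cfg <- train_config(lr = 2e-3, batch = 1, epochs = 4,
                      samples_per_phantom = 2, seed = 3)
  m1 <- train_racnet(m0, list(mk(1)), list(mk(2)), geom, cfg, n_val = 1)
  expect_equal(nrow(m1$history), 4)
  expect_lte(min(m1$history$val_loss), m1$history$val_loss[1])
  expect_error(train_racnet(m0, list(), list(mk(2)), geom, cfg), "non-empty")
})
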