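test_that("filter counts double per stage and the head is linear", {
  cfg <- unet_config(3, 4, 2, 3)
  lay <- samoco4d:::.cpp_unet_layout(unclass(cfg))
  # encoder conv output channels: 4,4, 8,8, 16,16
  expect_equal(lay$conv_out[1:6], c(4, 4, 8, 8, 16, 16))
  expect_equal(lay$conv_out[seq_len(6) * 0 + length(lay$conv_out)][1], 3)
  expect_equal(lay$conv_act[length(lay$conv_act)], 0)
  # parameter count is deterministic in the config
  m1 <- build_dvfnet(cfg, seed = 1)
  m2 <- build_dvfnet(cfg, seed = 1)
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params, build_dvfnet(cfg, seed = 2)$params))
})

test_that("forward pass honours the shape contract", {
  cfg <- unet_config(2, 4, 2, 3)
  m <- build_dvfnet(cfg, seed = 1)
  x <- array(rnorm(16 * 16 * 16 * 2), c(16, 16, 16, 2))
  y <- unet_forward(m, x)
  expect_equal(dim(y), c(16L, 16L, 16L, 3L))
  expect_error(unet_forward(m, array(0, c(15, 16, 16, 2))), "divisible")
  expect_error(unet_forward(m, array(0, c(16, 16, 16, 3))), "channel")
})

test_that("analytic gradients match finite differences", {
  cfg <- unet_config(2, 2, 2, 3)
  m <- build_dvfnet(cfg, seed = 3)
  set.seed(1)
  x <- array(runif(8 * 8 * 8 * 2), c(8, 8, 8, 2))
  y <- array(rnorm(8 * 8 * 8 * 3, sd = 0.1), c(8, 8, 8, 3))
  lg <- samoco4d:::.cpp_unet_loss_grad(m$params, x, y, unclass(cfg))
  eps <- 1e-6
  idx <- c(1L, 17L, length(m$params) %/% 2L, length(m$params) - 1L)
  for (i in idx) {
    p <- m$params
    p[i] <- p[i] + eps
    lp <- samoco4d:::.cpp_unet_loss_grad(p, x, y, unclass(cfg))$loss
    p[i] <- p[i] - 2 * eps
    lm <- samoco4d:::.cpp_unet_loss_grad(p, x, y, unclass(cfg))$loss
    expect_equal(lg$grad[i], (lp - lm) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("RAC residual contract: zero head is the identity", {
  cfg <- unet_config(2, 4, 1, 1)
  m <- build_racnet(cfg, seed = 1, zero_head = TRUE)
  grid <- volume_grid(16, 16, 8, 4)
  v <- volume(array(rnorm(16 * 16 * 8, sd = 100), c(16, 16, 8)), grid, "HU")
  out <- rac_apply(m, v)
  expect_equal(out$corrected$values, v$values, tolerance = 1e-12)
  expect_true(all(out$artifact == 0))
  # with a non-zero head: corrected - input == artifact, bitwise
  m2 <- build_racnet(cfg, seed = 2, zero_head = FALSE)
  out2 <- rac_apply(m2, v)
  expect_equal(out2$corrected$values - v$values, out2$artifact,
               tolerance = 1e-12)
})

test_that("DVF predictions convert voxel outputs to mm on the target grid", {
  cfg <- unet_config(2, 2, 2, 3)
  m <- build_dvfnet(cfg, seed = 5)
  grid <- volume_grid(16, 16, 8, 4)
  g1 <- volume(array(rnorm(16 * 16 * 8, sd = 100), c(16, 16, 8)), grid, "HU")
  g2 <- volume(array(rnorm(16 * 16 * 8, sd = 100), c(16, 16, 8)), grid, "HU")
  d <- predict_dvf(m, g1, g2)
  expect_s3_class(d, "dvf")
  raw <- unet_forward(m, samoco4d:::dvfnet_input(g1, g2))
  expect_equal(d$u, raw * 4, tolerance = 1e-12)
})

test_that("checkpoints round-trip config, kind and parameters", {
  m <- build_dvfnet(unet_config(2, 2, 2, 3), seed = 9)
  m$history <- data.frame(epoch = 1, train_loss = 0.5, val_loss = 0.6)
  path <- tempfile(fileext = ".json")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_equal(m2$params, m$params)
  expect_equal(m2$kind, "dvf")
  expect_equal(m2$cfg$n_stages, 2L)
  x <- array(runif(8 * 8 * 8 * 2), c(8, 8, 8, 2))
  expect_equal(unet_forward(m2, x), unet_forward(m, x))
})
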