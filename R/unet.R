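#' U-Net configuration
#'
#' Encoder-decoder with skip connections; each stage applies two 3x3x3
#' convolutions with PReLU activations, the filter count doubles per stage
#' starting from `base_filters`, downsampling is 2x2x2 max pooling and
#' upsampling 2x2x2 nearest neighbour; the head is a linear 3x3x3
#' convolution. The full-scale configuration uses 6 stages starting at 8
#' filters; the desk-scale default is smaller.
#'
#' @param n_stages number of resolution stages (input dims must be
#'   divisible by `2^(n_stages-1)`)
#' @param base_filters filters in the first stage
#' @param in_ch,out_ch input / output channels
#' @return an object of class `unet_config`
#' @export
unet_config <- function(n_stages = 4, base_filters = 8, in_ch = 2,
                        out_ch = 3) {
  if (n_stages < 1 || base_filters < 1) stop("invalid U-Net configuration")
  structure(list(n_stages = as.integer(n_stages),
                 base_filters = as.integer(base_filters),
                 in_ch = as.integer(in_ch), out_ch = as.integer(out_ch)),
            class = "unet_config")
}

# seeded He-style initialization following the layout reported by the C++
# side; PReLU slopes start at 0.25, biases at zero
unet_init_params <- function(cfg, seed) {
  lay <- .cpp_unet_layout(unclass(cfg))
  set.seed(seed)
  parts <- vector("list", length(lay$conv_out))
  for (i in seq_along(lay$conv_out)) {
    co <- lay$conv_out[i]; ci <- lay$conv_in[i]
    w <- rnorm(co * ci * 27, sd = sqrt(2 / (ci * 27)))
    b <- numeric(co)
    a <- if (lay$conv_act[i] == 1) rep(0.25, co) else numeric(0)
    parts[[i]] <- c(w, b, a)
  }
  p <- unlist(parts)
  stopifnot(length(p) == lay$n_params)
  p
}

#' Build the DVF-prediction network
#'
#' A U-Net mapping the two-channel input `(g_i, g_n)` (modified SARs of the
#' source and target motion state) to the three-component DVF `u_i^n`.
#' Inputs are normalized from `[-1000, 1000]` HU to `[0, 1]` (clipped);
#' the network predicts displacements in voxels, converted to mm at the
#' boundary, so weights are resolution-independent. Deterministic given
#' the seed.
#'
#' @param cfg a [unet_config()] with `in_ch = 2`, `out_ch = 3`
#' @param seed initialization seed
#' @return an object of class `unet_model` (kind `"dvf"`)
#' @export
build_dvfnet <- function(cfg = unet_config(4, 8, 2, 3), seed = 1) {
  stopifnot(cfg$in_ch == 2, cfg$out_ch == 3)
  structure(list(cfg = cfg, params = unet_init_params(cfg, seed),
                 kind = "dvf", seed = seed, history = NULL),
            class = "unet_model")
}

#' Build the residual artifact correction (RAC) network
#'
#' Same architecture as the DVF network but single input channel (the
#' SAMoCo reconstruction) and single output channel (the additive artifact
#' estimate A); applied through a residual connection,
#' `corrected = input + A`. A RAC net whose head weights are zero is
#' exactly the identity.
#'
#' @param cfg a [unet_config()] with `in_ch = 1`, `out_ch = 1`
#' @param seed initialization seed
#' @param zero_head zero the final convolution so the untrained network
#'   starts as the identity (default `TRUE`)
#' @return an object of class `unet_model` (kind `"rac"`)
#' @export
build_racnet <- function(cfg = unet_config(4, 8, 1, 1), seed = 1,
                         zero_head = TRUE) {
  stopifnot(cfg$in_ch == 1, cfg$out_ch == 1)
  p <- unet_init_params(cfg, seed)
  if (zero_head) {
    lay <- .cpp_unet_layout(unclass(cfg))
    nlast <- lay$conv_out[length(lay$conv_out)] *
      lay$conv_in[length(lay$conv_in)] * 27 +
      lay$conv_out[length(lay$conv_out)]
    p[(length(p) - nlast + 1):length(p)] <- 0
  }
  structure(list(cfg = cfg, params = p, kind = "rac", seed = seed,
                 history = NULL),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("U-Net (%s): %d stages, %d base filters, %d -> %d ch, %d parameters\n",
              x$kind, x$cfg$n_stages, x$cfg$base_filters, x$cfg$in_ch,
              x$cfg$out_ch, length(x$params)))
  invisible(x)
}

#' Raw network forward pass
#' @param model a `unet_model`
#' @param input numeric array `(nx, ny, nz, in_ch)`
#' @return array `(nx, ny, nz, out_ch)`
#' @export
unet_forward <- function(model, input) {
  d <- dim(input)
  if (length(d) == 3) dim(input) <- c(d, 1L)
  d <- dim(input)
  if (d[4] != model$cfg$in_ch) stop("channel count mismatch")
  div <- 2^(model$cfg$n_stages - 1)
  if (any(d[1:3] %% div != 0))
    stop(sprintf("spatial dims must be divisible by %d", div))
  .cpp_unet_forward(model$params, input, unclass(model$cfg))
}

# HU volumes -> [0, 1] network input scale (clipped)
normalize_hu <- function(hu) pmin(pmax((hu + 1000) / 2000, 0), 1)

#' Predict a DVF from two modified SARs
#'
#' Channel order is fixed: `(g_i, g_n)` (source first). The raw network
#' output in voxel units is rescaled to mm with the grid's voxel size.
#'
#' @param model a trained `unet_model` of kind `"dvf"`
#' @param g_i,g_n modified-SAR `ct_volume`s (any unit; converted to HU)
#' @return a `dvf` on `g_n`'s grid
#' @export
predict_dvf <- function(model, g_i, g_n) {
  stopifnot(model$kind == "dvf")
  if (!grids_equal(g_i$grid, g_n$grid)) stop("input grids differ")
  inp <- dvfnet_input(g_i, g_n)
  u_vox <- unet_forward(model, inp)
  dvf(u_vox * g_n$grid$voxel_size, g_n$grid)
}

# stack two volumes into the normalized 2-channel network input
dvfnet_input <- function(g_i, g_n) {
  a <- normalize_hu(convert_unit(g_i, "HU")$values)
  b <- normalize_hu(convert_unit(g_n, "HU")$values)
  array(c(a, b), c(dim(a), 2L))
}

#' Network-backed DVF provider
#'
#' Wraps a trained DVF network as a provider for [samoco_reconstruct()]:
#' modified SARs `g_i` are computed once per view from the scan and the
#' network predicts the field for each requested pair.
#'
#' @param model a trained `unet_model` of kind `"dvf"`
#' @param scan a `scan_record`
#' @param grid reconstruction `volume_grid` (must match the network's
#'   training resolution constraints)
#' @param fbar optional precomputed blurred reconstruction
#' @param eps guard for [modified_sar()]
#' @return a `dvf_provider`
#' @export
dvf_provider_network <- function(model, scan, grid, fbar = NULL,
                                 eps = 1e-4) {
  if (is.null(fbar)) fbar <- fdk_reconstruct(scan$projections, grid)
  n <- scan$projections$geometry$n_views
  cache <- vector("list", n)
  get_g <- function(i) {
    if (is.null(cache[[i]]))
      cache[[i]] <<- convert_unit(modified_sar(scan, i, fbar, eps = eps), "HU")
    cache[[i]]
  }
  f <- function(i, n_ref) predict_dvf(model, get_g(i), get_g(n_ref))
  structure(f, class = c("dvf_provider", "function"), mode = "network")
}

#' Apply the RAC network through its residual connection
#'
#' `corrected = input + A` where A is the network's artifact estimate.
#' The prediction is made on the normalized HU scale and mapped back.
#'
#' @param model a `unet_model` of kind `"rac"`
#' @param vol a `ct_volume` (SAMoCo reconstruction)
#' @return list with `corrected` (a `ct_volume`, HU) and `artifact`
#'   (HU array A)
#' @export
rac_apply <- function(model, vol) {
  stopifnot(model$kind == "rac")
  hu <- convert_unit(vol, "HU")
  inp <- array(normalize_hu(hu$values), c(dim(hu$values), 1L))
  a_norm <- unet_forward(model, inp)
  A <- a_norm[, , , 1] * 2000
  list(corrected = volume(hu$values + A, vol$grid, "HU"), artifact = A)
}

#' Save / load a model checkpoint (plain JSON: config + parameters +
#' training manifest)
#' @param model a `unet_model`
#' @param path file path
#' @return `load_checkpoint` returns a `unet_model`
#' @export
save_checkpoint <- function(model, path) {
  jsonlite::write_json(list(cfg = unclass(model$cfg), kind = model$kind,
                            seed = model$seed, params = model$params,
                            history = model$history),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- unet_config(m$cfg$n_stages, m$cfg$base_filters, m$cfg$in_ch,
                     m$cfg$out_ch)
  structure(list(cfg = cfg, params = as.numeric(m$params), kind = m$kind,
                 seed = m$seed, history = m$history),
            class = "unet_model")
}
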