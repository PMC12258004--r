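#' Training configuration
#'
#' Adam optimizer with MSE loss. The full-scale protocol for the DVF
#' network is 500 epochs with 1000 samples per phantom per epoch and batch
#' size four; for the RAC network 300 epochs, 50 sequences per phantom and
#' batch size one. The desk-scale defaults here are far smaller.
#'
#' @param lr learning rate
#' @param batch batch size
#' @param epochs number of epochs
#' @param samples_per_phantom samples drawn per phantom per epoch
#' @param seed training seed
#' @return an object of class `train_config`
#' @export
train_config <- function(lr = 1e-4, batch = 4, epochs = 10,
                         samples_per_phantom = 50, seed = 1) {
  if (lr <= 0 || batch < 1 || epochs < 1 || samples_per_phantom < 1)
    stop("training configuration values must be positive")
  structure(list(lr = lr, batch = as.integer(batch),
                 epochs = as.integer(epochs),
                 samples_per_phantom = as.integer(samples_per_phantom),
                 seed = as.integer(seed)), class = "train_config")
}

# one Adam step; state holds m, v, t
adam_step <- function(params, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  if (is.null(state))
    state <- list(m = numeric(length(params)), v = numeric(length(params)),
                  t = 0)
  state$t <- state$t + 1
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(params = params - lr * mhat / (sqrt(vhat) + eps), state = state)
}

#' Precompute the training context of a phantom
#'
#' Simulates one full scan of the phantom with a randomized periodic
#' breathing signal and reconstructs the motion-blurred initial volume
#' `fbar` used by all modified-SAR computations of that phantom.
#'
#' @param phantom a `phantom4d`
#' @param geom a `cone_beam_geometry`
#' @param seed seed for the randomized signal
#' @return list with `fbar` (attenuation `ct_volume`), `geom`, `phantom`,
#'   and the per-phase attenuation volumes
#' @export
phantom_train_context <- function(phantom, geom, seed = 1) {
  set.seed(seed)
  sig <- periodic_signal(geom$n_views, cycles = runif(1, 10, 18),
                         phase0 = runif(1, 1, 11 - 1e-9))
  scan <- simulate_scan(phantom, sig, geom)
  fbar <- fdk_reconstruct(scan$projections, phantom$grid)
  mu_phases <- lapply(phantom$phases, convert_unit, unit = "mu")
  list(fbar = fbar, geom = geom, phantom = phantom, mu_phases = mu_phases)
}

#' Draw one on-the-fly training pair for the DVF network
#'
#' Samples two phases (i, n) and two view angles uniformly, renders the
#' single-view projections of the two phase states, computes the modified
#' SARs `g_i`, `g_n` against the phantom's `fbar`, and returns them with
#' the exact phantom DVF `u_i^n` as label. Uses R's RNG stream (seed it
#' with `set.seed` for reproducibility).
#'
#' @param ctx a [phantom_train_context()]
#' @param eps modified-SAR guard
#' @return list with `g_i`, `g_n` (`ct_volume`s in HU), `label` (a `dvf`),
#'   and the drawn `(phase_i, phase_n, angle_i, angle_n)`
#' @export
sample_training_pair <- function(ctx, eps = 1e-4) {
  ph <- sample.int(10, 2, replace = TRUE)
  th <- runif(2, 0, 2 * pi)
  g <- vector("list", 2)
  for (k in 1:2) {
    geom1 <- ctx$geom
    geom1$angles <- th[k]
    geom1$n_views <- 1L
    p <- forward_project(ctx$mu_phases[[ph[k]]], geom1, 1)
    sc <- list(projections = p)
    g[[k]] <- convert_unit(modified_sar(sc, 1, ctx$fbar, eps = eps), "HU")
  }
  label <- dvf_between(ctx$phantom, ph[1], ph[2])
  list(g_i = g[[1]], g_n = g[[2]], label = label,
       phase_i = ph[1], phase_n = ph[2], angle_i = th[1], angle_n = th[2])
}

#' Train the DVF-prediction network
#'
#' Minimizes the MSE between predicted and ground-truth DVFs on pairs
#' drawn on the fly from the training phantoms; after each epoch the loss
#' on a fixed validation-set draw is evaluated and the best-performing
#' parameters are kept (validation-selected checkpoint). Deterministic
#' given the config seed (single-threaded).
#'
#' @param model a `unet_model` of kind `"dvf"`
#' @param train_ctx list of [phantom_train_context()]s (training phantoms)
#' @param val_ctx list of contexts for disjoint validation phantoms
#' @param cfg a [train_config()]
#' @param n_val validation pairs drawn per validation phantom
#' @return the model with `history` (per-epoch train/val loss) and
#'   validation-best parameters
#' @export
train_dvfnet <- function(model, train_ctx, val_ctx, cfg = train_config(),
                         n_val = 8) {
  stopifnot(model$kind == "dvf")
  if (length(train_ctx) == 0 || length(val_ctx) == 0)
    stop("training and validation sets must be non-empty")
  vs <- train_ctx[[1]]$phantom$grid$voxel_size
  set.seed(cfg$seed)
  val_pairs <- unlist(lapply(val_ctx, function(cx)
    replicate(n_val, sample_training_pair(cx), simplify = FALSE)),
    recursive = FALSE)
  state <- NULL
  best <- list(loss = Inf, params = model$params)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  ucfg <- unclass(model$cfg)
  pair_io <- function(pr) {
    list(x = dvfnet_input(pr$g_i, pr$g_n), y = pr$label$u / vs)
  }
  val_io <- lapply(val_pairs, pair_io)
  for (ep in seq_len(cfg$epochs)) {
    tr_loss <- 0; n_samp <- 0
    batch_grad <- NULL; batch_n <- 0
    for (cx in train_ctx) {
      for (s in seq_len(cfg$samples_per_phantom)) {
        io <- pair_io(sample_training_pair(cx))
        lg <- .cpp_unet_loss_grad(model$params, io$x, io$y, ucfg)
        tr_loss <- tr_loss + lg$loss; n_samp <- n_samp + 1
        batch_grad <- if (is.null(batch_grad)) lg$grad
                      else batch_grad + lg$grad
        batch_n <- batch_n + 1
        if (batch_n == cfg$batch) {
          st <- adam_step(model$params, batch_grad / batch_n, state, cfg$lr)
          model$params <- st$params; state <- st$state
          batch_grad <- NULL; batch_n <- 0
        }
      }
    }
    if (batch_n > 0) {
      st <- adam_step(model$params, batch_grad / batch_n, state, cfg$lr)
      model$params <- st$params; state <- st$state
    }
    vl <- mean(vapply(val_io, function(io)
      .cpp_unet_loss_grad(model$params, io$x, io$y, ucfg)$loss, 0))
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = tr_loss / n_samp,
                                   val_loss = vl))
    if (vl < best$loss) best <- list(loss = vl, params = model$params)
  }
  model$params <- best$params
  model$history <- hist
  model
}

#' Generate one RAC training example
#'
#' Samples a random integer-phase sequence (one uniform phase per view),
#' simulates the scan, reconstructs it with SAMoCo using the exact oracle
#' DVFs, and pairs it with the ideal-motion-compensation label: the FDK
#' reconstruction of a static scan of the reference state (equivalently,
#' the reconstruction in which every view's content already is the
#' reference state, i.e. the residual-free target).
#'
#' @param phantom a `phantom4d`
#' @param geom a `cone_beam_geometry`
#' @param ref_view reference view; default drawn uniformly
#' @return list with `input` and `label` (`ct_volume`s, HU), the phase
#'   sequence and the reference view. Uses R's RNG stream.
#' @export
make_rac_example <- function(phantom, geom, ref_view = NULL) {
  nv <- geom$n_views
  seq_ph <- sample.int(10, nv, replace = TRUE)
  if (is.null(ref_view)) ref_view <- sample.int(nv, 1)
  sig <- phase_signal(as.numeric(seq_ph))
  scan <- simulate_scan(phantom, sig, geom)
  grid <- phantom$grid
  # oracle SAMoCo: only 10 distinct DVFs (integer phases -> reference phase)
  ref_ph <- seq_ph[ref_view]
  dvfs <- lapply(1:10, function(p) dvf_between(phantom, p, ref_ph))
  provider <- structure(function(i, n) dvfs[[seq_ph[i]]],
                        class = c("dvf_provider", "function"),
                        mode = "oracle")
  input <- samoco_reconstruct(scan, provider, ref_view, grid)
  static <- simulate_scan(phantom, phase_signal(rep(ref_ph, nv)), geom)
  label <- fdk_reconstruct(static$projections, grid)
  list(input = convert_unit(input, "HU"), label = convert_unit(label, "HU"),
       phases = seq_ph, ref_view = ref_view)
}

#' Train the residual artifact correction network
#'
#' A fixed set of random-sequence examples (`samples_per_phantom` per
#' phantom, generated once) is iterated over for the configured number of
#' epochs, minimizing the MSE between the residually corrected SAMoCo
#' volume and the ideal-motion-compensation label; validation-best
#' parameters are kept. Because the network output enters through the
#' residual connection, it is trained to predict `label - input` on the
#' normalized scale.
#'
#' @param model a `unet_model` of kind `"rac"`
#' @param train_phantoms list of `phantom4d` (training)
#' @param val_phantoms disjoint list for validation
#' @param geom a `cone_beam_geometry`
#' @param cfg a [train_config()] (`samples_per_phantom` = sequences per
#'   phantom; `batch` is typically 1)
#' @param n_val validation examples per validation phantom
#' @param patch optional length-3 patch size (voxels, divisible by
#'   `2^(n_stages-1)`): train on randomly cropped patches of the examples
#'   instead of full volumes -- many cheap steps with full-resolution
#'   features; the fully convolutional network still applies to whole
#'   volumes at inference
#' @param patches_per_epoch patches drawn per epoch when `patch` is given
#' @return the trained model with history
#' @export
train_racnet <- function(model, train_phantoms, val_phantoms, geom,
                         cfg = train_config(batch = 1), n_val = 2,
                         patch = NULL, patches_per_epoch = 64) {
  stopifnot(model$kind == "rac")
  if (length(train_phantoms) == 0 || length(val_phantoms) == 0)
    stop("training and validation sets must be non-empty")
  set.seed(cfg$seed)
  ex_io <- function(ex) {
    x <- array(normalize_hu(ex$input$values), c(dim(ex$input$values), 1L))
    y <- array((ex$label$values - ex$input$values) / 2000,
               c(dim(ex$label$values), 1L))
    list(x = x, y = y)
  }
  train_io <- unlist(lapply(train_phantoms, function(ph)
    replicate(cfg$samples_per_phantom, ex_io(make_rac_example(ph, geom)),
              simplify = FALSE)), recursive = FALSE)
  val_io <- unlist(lapply(val_phantoms, function(ph)
    replicate(n_val, ex_io(make_rac_example(ph, geom)), simplify = FALSE)),
    recursive = FALSE)
  if (!is.null(patch)) {
    div <- 2^(model$cfg$n_stages - 1)
    if (any(patch %% div != 0))
      stop(sprintf("patch dims must be divisible by %d", div))
  }
  crop <- function(io, at = NULL) {
    d <- dim(io$x)[1:3]
    if (is.null(at))
      at <- vapply(1:3, function(a) sample.int(d[a] - patch[a] + 1, 1), 0L)
    ix <- lapply(1:3, function(a) at[a]:(at[a] + patch[a] - 1))
    list(x = io$x[ix[[1]], ix[[2]], ix[[3]], , drop = FALSE],
         y = io$y[ix[[1]], ix[[2]], ix[[3]], , drop = FALSE])
  }
  state <- NULL
  best <- list(loss = Inf, params = model$params)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  ucfg <- unclass(model$cfg)
  for (ep in seq_len(cfg$epochs)) {
    draws <- if (is.null(patch)) sample.int(length(train_io))
             else sample.int(length(train_io), patches_per_epoch,
                             replace = TRUE)
    tr_loss <- 0
    batch_grad <- NULL; batch_n <- 0
    for (j in draws) {
      io <- if (is.null(patch)) train_io[[j]] else crop(train_io[[j]])
      lg <- .cpp_unet_loss_grad(model$params, io$x, io$y, ucfg)
      tr_loss <- tr_loss + lg$loss
      batch_grad <- if (is.null(batch_grad)) lg$grad else batch_grad + lg$grad
      batch_n <- batch_n + 1
      if (batch_n == cfg$batch) {
        st <- adam_step(model$params, batch_grad / batch_n, state, cfg$lr)
        model$params <- st$params; state <- st$state
        batch_grad <- NULL; batch_n <- 0
      }
    }
    if (batch_n > 0) {
      st <- adam_step(model$params, batch_grad / batch_n, state, cfg$lr)
      model$params <- st$params; state <- st$state
    }
    # validation on full volumes (the network is fully convolutional)
    vl <- mean(vapply(val_io, function(io)
      .cpp_unet_loss_grad(model$params, io$x, io$y, ucfg)$loss, 0))
    hist <- rbind(hist, data.frame(epoch = ep,
                                   train_loss = tr_loss / length(draws),
                                   val_loss = vl))
    if (vl < best$loss) best <- list(loss = vl, params = model$params)
  }
  model$params <- best$params
  model$history <- hist
  model
}
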