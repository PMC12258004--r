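#' Workflow configuration
#'
#' A single serializable record driving the end-to-end workflows; written
#' into every artifact directory together with its hash so runs can be
#' reproduced bit-identically.
#'
#' @param seed master seed
#' @param grid_n voxel counts (length 3)
#' @param voxel_mm voxel size
#' @param n_views views per scan
#' @param excursion diaphragm excursion, mm
#' @param cycles periodic-signal breathing cycles
#' @param out output directory
#' @param ... further fields kept verbatim
#' @return an object of class `workflow_config`
#' @export
workflow_config <- function(seed = 1, grid_n = c(64, 64, 48), voxel_mm = 3,
                            n_views = 164, excursion = 15, cycles = 15,
                            out = tempfile("samoco_"), ...) {
  cfg <- list(seed = seed, grid_n = grid_n, voxel_mm = voxel_mm,
              n_views = n_views, excursion = excursion, cycles = cycles,
              out = out, ...)
  class(cfg) <- "workflow_config"
  cfg
}

cfg_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  # small rolling hash; enough to detect config drift in provenance files
  sum(utf8ToInt(as.character(s)) * (seq_len(nchar(s)) %% 97 + 1)) %% 1e9
}

write_provenance <- function(cfg, dir, extra = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prov <- c(list(config = unclass(cfg), config_hash = cfg_hash(cfg),
                 package_version = as.character(utils::packageVersion("samoco4d"))),
            extra)
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Toy demonstration of the residual-streak mechanism
#'
#' Simulates the periodically scaled cylinder scan, reconstructs it with
#' plain FDK (motion-corrupted), with SAMoCo using the exact inverse of
#' the scaling motion (motion compensated, residual streaks remain), and
#' compares both against the static reference state. Writes center-slice
#' images (CSV matrices) and metrics.
#'
#' @param cfg a [workflow_config()]; respected fields: `seed`, `grid_n`,
#'   `voxel_mm`, `n_views`, `out`, optional `amplitude`, `freq`
#' @return invisibly, the metrics list
#' @export
run_toy_demo <- function(cfg = workflow_config()) {
  amp <- if (is.null(cfg$amplitude)) 0.1 else cfg$amplitude
  freq <- if (is.null(cfg$freq)) 0.15 else cfg$freq
  grid <- volume_grid(cfg$grid_n[1], cfg$grid_n[2], cfg$grid_n[3],
                      cfg$voxel_mm)
  geom <- scaled_geometry(n_views = cfg$n_views)
  set.seed(cfg$seed)
  scan <- simulate_toy_scan(grid, geom, amplitude = amp, freq = freq)
  ref <- 1L
  truth <- convert_unit(make_toy_phantom(grid, scan$inserts, scan$radius,
                                         scale = scan$scales[ref]), "mu")
  fdk <- fdk_reconstruct(scan$projections, grid)
  prov <- dvf_provider_toy(scan$scales, grid)
  sam <- samoco_reconstruct(scan, prov, ref, grid)
  static_scan <- simulate_toy_scan(grid, geom, amplitude = 0)
  static_fdk <- fdk_reconstruct(static_scan$projections, grid)
  msk <- make_toy_phantom(grid, scan$inserts, scan$radius,
                          scale = scan$scales[ref])$values > -500
  met <- list(
    fdk_mae = mae_hu(fdk, truth, msk),
    samoco_mae = mae_hu(sam, truth, msk),
    static_mae = mae_hu(static_fdk,
                        convert_unit(make_toy_phantom(grid, scan$inserts,
                                                      scan$radius), "mu"),
                        msk))
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  mid <- ceiling(grid$nz / 2)
  utils::write.csv(mu_to_hu(fdk$values[, , mid]),
                   file.path(cfg$out, "slice_fdk.csv"), row.names = FALSE)
  utils::write.csv(mu_to_hu(sam$values[, , mid]),
                   file.path(cfg$out, "slice_samoco.csv"), row.names = FALSE)
  utils::write.csv(mu_to_hu(truth$values[, , mid]),
                   file.path(cfg$out, "slice_truth.csv"), row.names = FALSE)
  jsonlite::write_json(met, file.path(cfg$out, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  write_provenance(cfg, cfg$out)
  invisible(met)
}

#' Periodic / non-periodic simulation study
#'
#' For both signal types: simulates a thorax scan, reconstructs a set of
#' evenly spaced reference states with gated reconstruction (20\% window)
#' and oracle-DVF SAMoCo (optionally + a RAC model), and writes the
#' metric grid and per-state diaphragm curves.
#'
#' @param cfg a [workflow_config()]; optional fields: `n_states` (default
#'   10), `rac_model` (a trained RAC `unet_model`), `window_fraction`
#' @return invisibly, a data.frame with one row per (signal, method)
#' @export
run_simulation_study <- function(cfg = workflow_config()) {
  grid <- volume_grid(cfg$grid_n[1], cfg$grid_n[2], cfg$grid_n[3],
                      cfg$voxel_mm)
  geom <- scaled_geometry(n_views = cfg$n_views)
  n_states <- if (is.null(cfg$n_states)) 10 else cfg$n_states
  wfrac <- if (is.null(cfg$window_fraction)) 0.2 else cfg$window_fraction
  phantom <- make_thorax_phantom(grid,
                                 thorax_params(excursion = cfg$excursion,
                                               seed = cfg$seed),
                                 seed = cfg$seed)
  signals <- list(periodic = periodic_signal(cfg$n_views, cfg$cycles),
                  nonperiodic = nonperiodic_signal(cfg$n_views,
                                                   seed = cfg$seed))
  grid_rows <- data.frame()
  for (sname in names(signals)) {
    scan <- simulate_scan(phantom, signals[[sname]], geom)
    refs <- unique(round(seq(1, cfg$n_views, length.out = n_states)))
    oracle <- dvf_provider_oracle(scan, grid)
    sams <- samoco_4d(scan, oracle, refs, grid, window = "ramlak")
    recons <- list(samoco = sams)
    gated <- vector("list", length(refs))
    for (j in seq_along(refs)) {
      gated[[j]] <- tryCatch(
        gated_reconstruct(scan, gating_window(scan$signal$phi[refs[j]],
                                              wfrac), grid,
                          filter_window = "ramlak"),
        error = function(e) NULL)
    }
    if (!any(vapply(gated, is.null, TRUE))) recons$gated <- gated
    if (!is.null(cfg$rac_model))
      recons$samoco_rac <- lapply(sams, function(v)
        convert_unit(rac_apply(cfg$rac_model, v)$corrected, "mu"))
    out_s <- file.path(cfg$out, sname)
    met <- evaluation_report(scan, recons, refs, out_s, seed = cfg$seed)
    met$signal <- sname
    grid_rows <- rbind(grid_rows, met)
  }
  utils::write.csv(grid_rows, file.path(cfg$out, "metric_grid.csv"),
                   row.names = FALSE)
  jsonlite::write_json(grid_rows, file.path(cfg$out, "metric_grid.json"),
                       dataframe = "rows", digits = NA)
  write_provenance(cfg, cfg$out)
  invisible(grid_rows)
}

#' End-to-end training workflow
#'
#' Generates disjoint phantom families (train / validation / held-out
#' test), trains the DVF network and the RAC network, evaluates DVF
#' accuracy per anatomical class on the held-out phantoms, and writes
#' checkpoints plus the accuracy table.
#'
#' @param cfg a [workflow_config()]; optional fields: `n_train`, `n_val`,
#'   `n_test`, `net_stages`, `net_filters`, `dvf_epochs`, `rac_epochs`,
#'   `samples_per_phantom`, `rac_sequences`, `train_views`
#' @return invisibly, a list with both models and the held-out DVF table
#' @export
run_training <- function(cfg = workflow_config(grid_n = c(32, 32, 16),
                                               voxel_mm = 6, n_views = 60)) {
  gv <- function(f, d) if (is.null(cfg[[f]])) d else cfg[[f]]
  n_train <- gv("n_train", 3); n_val <- gv("n_val", 1); n_test <- gv("n_test", 1)
  grid <- volume_grid(cfg$grid_n[1], cfg$grid_n[2], cfg$grid_n[3],
                      cfg$voxel_mm)
  geom <- scaled_geometry(n_views = gv("train_views", cfg$n_views))
  mk <- function(s) make_thorax_phantom(
    grid, thorax_params(excursion = cfg$excursion, seed = s), seed = s)
  seeds <- cfg$seed * 1000 + seq_len(n_train + n_val + n_test)
  phs <- lapply(seeds, mk)
  tr <- phs[seq_len(n_train)]
  va <- phs[n_train + seq_len(n_val)]
  te <- phs[n_train + n_val + seq_len(n_test)]
  tr_ctx <- lapply(seq_along(tr), function(i)
    phantom_train_context(tr[[i]], geom, seed = cfg$seed + i))
  va_ctx <- lapply(seq_along(va), function(i)
    phantom_train_context(va[[i]], geom, seed = cfg$seed + 100 + i))
  dvf_model <- build_dvfnet(unet_config(gv("net_stages", 3),
                                        gv("net_filters", 8), 2, 3),
                            seed = cfg$seed)
  dvf_model <- train_dvfnet(dvf_model, tr_ctx, va_ctx,
                            train_config(epochs = gv("dvf_epochs", 10),
                                         samples_per_phantom =
                                           gv("samples_per_phantom", 30),
                                         seed = cfg$seed))
  rac_model <- build_racnet(unet_config(gv("net_stages", 3),
                                        gv("net_filters", 8), 1, 1),
                            seed = cfg$seed)
  rac_model <- train_racnet(rac_model, tr, va, geom,
                            train_config(batch = 1,
                                         epochs = gv("rac_epochs", 6),
                                         samples_per_phantom =
                                           gv("rac_sequences", 4),
                                         seed = cfg$seed))
  # held-out DVF accuracy per class
  te_ctx <- lapply(seq_along(te), function(i)
    phantom_train_context(te[[i]], geom, seed = cfg$seed + 200 + i))
  set.seed(cfg$seed + 999)
  preds <- list(); gts <- list(); labs <- list()
  for (cx in te_ctx) {
    for (k in 1:10) {
      pr <- sample_training_pair(cx)
      preds <- c(preds, list(predict_dvf(dvf_model, pr$g_i, pr$g_n)))
      gts <- c(gts, list(pr$label))
      labs <- c(labs, list(cx$phantom$labels[[pr$phase_n]]))
    }
  }
  tab <- dvf_class_stats(preds, gts, labs)
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  save_checkpoint(dvf_model, file.path(cfg$out, "dvfnet.json"))
  save_checkpoint(rac_model, file.path(cfg$out, "racnet.json"))
  utils::write.csv(tab, file.path(cfg$out, "dvf_accuracy.csv"),
                   row.names = FALSE)
  write_provenance(cfg, cfg$out,
                   extra = list(held_out_dvf_mae =
                                  mean(tab$mae[tab$class != "remainder"])))
  invisible(list(dvf_model = dvf_model, rac_model = rac_model,
                 dvf_table = tab))
}
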