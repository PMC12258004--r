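# Desk-scale simulation-study fixture shared by the acceptance tests:
# one held-out thorax phantom, periodic and non-periodic breathing scans,
# oracle-DVF SAMoCo reconstructions of evenly spaced reference states, and
# the gated baseline, all at the package's test study conditions
# (64 x 64 x 48 @ 3 mm, 160 x 120 detector @ 2 mm, 164 views, band-limited
# ramp kernel).

study_grid <- function() volume_grid(64, 64, 48, 3)

study_geom <- function(n_views = 164) {
  scaled_geometry(n_views = n_views, n_u = 160, n_v = 120, pixel_mm = 2.0)
}

study_phantom <- function(seed = 101) {
  make_thorax_phantom(study_grid(),
                      thorax_params(excursion = 15, seed = seed,
                                    edge_mm = 4), seed = seed)
}

study_fixture <- function() memo("study", {
  grid <- study_grid()
  geom <- study_geom()
  phantom <- study_phantom()
  out <- list(phantom = phantom, grid = grid, geom = geom)
  signals <- list(periodic = periodic_signal(164, cycles = 15),
                  nonperiodic = nonperiodic_signal(164, seed = 7))
  # reference states evenly spaced over the breathing cycle: the views
  # whose phases lie nearest to the target phases (end-exhale, mid-cycle,
  # end-inhale)
  target_phases <- c(1, 3.5, 6)
  for (sname in names(signals)) {
    scan <- simulate_scan(phantom, signals[[sname]], geom)
    refs <- vapply(target_phases, function(p)
      which.min(samoco4d:::phase_distance(scan$signal$phi, p)), 0L)
    sars <- compute_sars(scan, grid, window = "ramlak")
    oracle <- dvf_provider_oracle(scan, grid)
    res <- list(scan = scan, refs = refs, sam = list(), gt = list(),
                sam_mae = numeric(), sam_dia = numeric(),
                gated_mae = numeric(), gated_dia = numeric())
    for (j in seq_along(refs)) {
      r <- refs[j]
      sam <- convert_unit(
        samoco_reconstruct(scan, oracle, r, grid, sars = sars,
                           window = "ramlak"), "HU")
      gt <- scan_gt_volume(scan, r, with_labels = TRUE)
      msk <- body_mask(gt$labels)
      dp_gt <- diaphragm_position(gt$volume, gt$labels, 200, seed = 3)
      dp_sam <- diaphragm_position(sam, gt$labels, 200, seed = 3)
      res$sam[[j]] <- sam
      res$gt[[j]] <- gt
      res$sam_mae[j] <- mae_hu(sam, gt$volume, msk)
      res$sam_dia[j] <- abs(dp_sam$position - dp_gt$position)
      gated <- tryCatch(convert_unit(
        gated_reconstruct(scan, gating_window(scan$signal$phi[r], 0.2),
                          grid, filter_window = "ramlak"), "HU"),
        error = function(e) NULL)
      if (!is.null(gated)) {
        dp_g <- suppressWarnings(
          diaphragm_position(gated, gt$labels, 200, seed = 3))
        res$gated_mae[j] <- mae_hu(gated, gt$volume, msk)
        res$gated_dia[j] <- abs(dp_g$position - dp_gt$position)
      } else {
        res$gated_mae[j] <- NA_real_
        res$gated_dia[j] <- NA_real_
      }
    }
    out[[sname]] <- res
  }
  out
})
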