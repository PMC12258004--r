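#' Gating window
#'
#' A cyclic phase window: a view with phase `phi` belongs to the window if
#' its cyclic distance to `center_phase` is at most half of
#' `width_fraction` of the 10-phase cycle (window closed on both ends).
#'
#' @param center_phase real phase in `[1, 11)`
#' @param width_fraction fraction of the breathing cycle (default 0.20,
#'   i.e. a 20\% window)
#' @return an object of class `gating_window`
#' @export
gating_window <- function(center_phase, width_fraction = 0.20) {
  if (center_phase < 1 || center_phase >= 11) stop("center phase in [1,11)")
  if (width_fraction <= 0 || width_fraction > 1)
    stop("width_fraction must lie in (0, 1]")
  structure(list(center_phase = center_phase,
                 width_fraction = width_fraction), class = "gating_window")
}

# cyclic distance between phases on the [1, 11) circle, in phase units
phase_distance <- function(a, b) {
  d <- abs(a - b) %% 10
  pmin(d, 10 - d)
}

#' Views selected by a gating window
#' @param signal a `phase_signal`
#' @param window a `gating_window`
#' @return integer view indices
#' @export
gated_views <- function(signal, window) {
  half <- window$width_fraction * 10 / 2
  which(phase_distance(signal$phi, window$center_phase) <= half)
}

#' Retrospectively gated reconstruction
#'
#' FDK-style sum over the views whose phase lies inside the cyclic gating
#' window. By default the selected subset is re-calibrated with Voronoi
#' angular weights (each selected view weighted by half the angular gap to
#' its selected neighbours) so sparse subsets stay quantitatively correct;
#' `renormalize = FALSE` keeps the full-scan uniform weights instead.
#' With a full-cycle window the result equals [fdk_reconstruct()].
#'
#' @param scan a `scan_record`
#' @param window a `gating_window`
#' @param grid reconstruction `volume_grid`
#' @param renormalize use subset Voronoi weights (default `TRUE`)
#' @param filter_window ramp apodization passed to [fdk_reconstruct()]
#' @return a `ct_volume` in attenuation units
#' @export
gated_reconstruct <- function(scan, window, grid, renormalize = TRUE,
                              filter_window = "cosine") {
  sel <- gated_views(scan$signal, window)
  if (length(sel) == 0)
    stop(sprintf("empty gating bin: no views near phase %.2f",
                 window$center_phase))
  geom <- scan$geometry
  w <- if (renormalize) angular_weights(geom$angles[sel])
       else angular_weights(geom$angles)[sel]
  fdk_reconstruct(scan$projections, grid, window = filter_window,
                  view_indices = sel, view_weights = w)
}

#' Modified SAR: single-view SART-type update
#'
#' Enriches the i-th view's temporal information with the tomographic
#' context of an initial motion-blurred reconstruction `fbar`:
#' \deqn{g_i = \bar f + \frac{X_i^T\big((p_i - X_i \bar f)/(X_i 1)\big)}{X_i^T 1},}
#' the first update of a SART iteration for view i. Divisions are guarded
#' by `eps`; voxels outside the view's cone (where `X_i^T 1` vanishes)
#' keep the value of `fbar`. For data consistent with `fbar`
#' (`p_i == X_i fbar`) the update returns `fbar` unchanged.
#'
#' @param scan a `scan_record` (or any list with `projections`)
#' @param i view index
#' @param fbar initial reconstruction (`ct_volume`, attenuation units) on
#'   the target grid
#' @param eps guard for the ray-sum and cone divisions (> 0)
#' @param step ray sampling step, mm
#' @return a `ct_volume` in attenuation units
#' @export
modified_sar <- function(scan, i, fbar, eps = 1e-4,
                         step = fbar$grid$voxel_size / 2) {
  if (eps <= 0) stop("eps must be positive")
  proj <- scan$projections
  geom <- proj$geometry
  grid <- fbar$grid
  ones <- volume(array(1, c(grid$nx, grid$ny, grid$nz)), grid, "mu")
  p_i <- proj$frames[, , i]
  Xf <- forward_project(fbar, geom, i, step = step)$frames[, , 1]
  X1 <- forward_project(ones, geom, i, step = step)$frames[, , 1]
  resid <- (p_i - Xf) / pmax(X1, eps)
  resid[X1 < eps] <- 0
  rp <- projection_set(array(resid, c(geom$n_u, geom$n_v, 1)),
                       single_view_geom(geom, i))
  num <- backproject_single_unfiltered(rp, 1, grid, step = step)$values
  op <- projection_set(array(1, c(geom$n_u, geom$n_v, 1)),
                       single_view_geom(geom, i))
  den <- backproject_single_unfiltered(op, 1, grid, step = step)$values
  upd <- num / pmax(den, eps)
  upd[den < eps] <- 0  # outside the view's cone: keep fbar
  volume(fbar$values + upd, grid, "mu")
}

# geometry restricted to one view (keeps detector layout)
single_view_geom <- function(geom, i) {
  g <- geom
  g$angles <- geom$angles[i]
  g$n_views <- 1L
  g
}

#' DVF providers for SAMoCo reconstruction
#'
#' A DVF provider is a function `(i, n) -> dvf` returning, on the
#' reconstruction grid, the field that warps view i's SAR into the motion
#' state of reference view n. Providers share one call signature so the
#' oracle, the toy-analytic motion law, and a trained network are
#' interchangeable inside [samoco_reconstruct()].
#'
#' @param scan a `scan_record`
#' @param grid reconstruction `volume_grid`
#' @return a function of class `dvf_provider`
#' @export
dvf_provider_oracle <- function(scan, grid) {
  force(scan); force(grid)
  f <- function(i, n) {
    a_src <- amplitude_of(scan$phantom, scan$signal$phi[i])
    a_tgt <- amplitude_of(scan$phantom, scan$signal$phi[n])
    u <- .cpp_thorax_dvf(unclass(grid), scan$phantom$params, a_src, a_tgt)
    dvf(u, grid, source = i, target = n)
  }
  structure(f, class = c("dvf_provider", "function"), mode = "oracle")
}

#' @rdname dvf_provider_oracle
#' @export
dvf_provider_zero <- function(grid) {
  force(grid)
  z <- zero_dvf(grid)
  structure(function(i, n) z, class = c("dvf_provider", "function"),
            mode = "zero")
}

#' @rdname dvf_provider_oracle
#' @param scales per-view scale factors of a toy scan
#' @param center scaling fixed point
#' @export
dvf_provider_toy <- function(scales, grid, center = c(0, 0)) {
  force(scales); force(grid); force(center)
  f <- function(i, n) {
    scaling_dvf(affine_scaling(scales[i], center),
                affine_scaling(scales[n], center), grid)
  }
  structure(f, class = c("dvf_provider", "function"), mode = "toy-analytic")
}

#' Compute (and cache) all single-angle reconstructions of a scan
#'
#' 4D reconstruction reuses every SAR for each reference state, so they
#' are computed once. With `cache_dir` given, SARs are additionally
#' persisted to disk keyed by view index and reused across calls.
#'
#' @param scan a `scan_record` or `toy_scan`
#' @param grid reconstruction `volume_grid`
#' @param window ramp apodization window
#' @param cache_dir optional directory for on-disk caching
#' @return list of `ct_volume`s, one per view
#' @export
compute_sars <- function(scan, grid, window = "cosine", cache_dir = NULL) {
  proj <- scan$projections
  n <- proj$geometry$n_views
  w <- angular_weights(proj$geometry$angles)
  filt <- filter_frames(proj$frames, proj$geometry, window)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    key <- if (!is.null(cache_dir))
      file.path(cache_dir, sprintf("sar_%05d.rds", i)) else NULL
    if (!is.null(key) && file.exists(key)) {
      out[[i]] <- readRDS(key)
    } else {
      vals <- .cpp_backproject_fdk(filt[, , i, drop = FALSE], unclass(grid),
                                   unclass(proj$geometry),
                                   as.integer(i) - 1L, w[i])
      out[[i]] <- volume(vals, grid, "mu")
      if (!is.null(key)) {
        dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
        saveRDS(out[[i]], key)
      }
    }
  }
  out
}

#' SAMoCo reconstruction: warped sum of single-angle reconstructions
#'
#' Reconstructs the motion state of reference view `ref_view` by warping
#' every view's SAR into that state with the provider's DVF and summing:
#' \deqn{f_{n,SAMoCo} = \sum_i T_i^n \circ X_i^{-1} p_i.}
#' With zero DVFs this reduces exactly to [fdk_reconstruct()]. Any view can
#' serve as the reference, giving single-view temporal resolution.
#'
#' @param scan a `scan_record` or `toy_scan`
#' @param provider a `dvf_provider`
#' @param ref_view reference view index
#' @param grid reconstruction `volume_grid`
#' @param sars optional precomputed SAR list from [compute_sars()]
#' @param window ramp apodization window
#' @return a `ct_volume` in attenuation units
#' @export
samoco_reconstruct <- function(scan, provider, ref_view, grid, sars = NULL,
                               window = "cosine") {
  n <- scan$projections$geometry$n_views
  if (ref_view < 1 || ref_view > n) stop("ref_view out of range")
  if (is.null(sars)) sars <- compute_sars(scan, grid, window)
  acc <- array(0, c(grid$nx, grid$ny, grid$nz))
  for (i in seq_len(n)) {
    d <- tryCatch(provider(i, ref_view), error = function(e)
      stop(sprintf("DVF provider failed for pair (%d, %d): %s", i, ref_view,
                   conditionMessage(e))))
    acc <- acc + .cpp_warp(sars[[i]]$values, d$u, grid$voxel_size)
  }
  volume(acc, grid, "mu")
}

#' 4D SAMoCo reconstruction over a set of reference views
#'
#' Maps [samoco_reconstruct()] over `ref_views`, computing the SARs once.
#'
#' @inheritParams samoco_reconstruct
#' @param ref_views vector of reference view indices
#' @param cache_dir optional SAR disk cache
#' @return list of `ct_volume`s, one per reference view
#' @export
samoco_4d <- function(scan, provider, ref_views, grid, window = "cosine",
                      cache_dir = NULL) {
  sars <- compute_sars(scan, grid, window, cache_dir)
  lapply(ref_views, function(r)
    samoco_reconstruct(scan, provider, r, grid, sars = sars, window = window))
}
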