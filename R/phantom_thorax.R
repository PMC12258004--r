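#' Anatomy and motion parameters for the digital thorax phantom
#'
#' Geometric and intensity parameters (mm / HU) of the deformable thorax
#' phantom plus its breathing model. With `seed` given, moderate anatomical
#' variability (body habitus, lung size, dome height, heart position,
#' nodule placement) is drawn reproducibly, emulating a patient population.
#'
#' @param excursion peak-to-peak diaphragm displacement, mm (5-25)
#' @param n_nodules number of lung nodules
#' @param ap_fraction anterior chest expansion as a fraction of `excursion`
#' @param seed integer seed for anatomical variability; `NULL` keeps the
#'   nominal anatomy
#' @param edge_mm smooth tissue-boundary blend width, mm
#' @return a named list of phantom parameters
#' @export
thorax_params <- function(excursion = 15, n_nodules = 3, ap_fraction = 0.15,
                          seed = NULL, edge_mm = 2) {
  if (excursion < 0 || excursion > 40)
    stop("excursion outside supported range (0-40 mm)")
  jit <- function(lo, hi) if (is.null(seed)) (lo + hi) / 2 else runif(1, lo, hi)
  if (!is.null(seed)) set.seed(seed)
  body_ax <- jit(80, 90); body_ay <- jit(56, 64); body_az <- jit(62, 68)
  dome_z <- jit(-14, -6)
  p <- list(
    body_ax = body_ax, body_ay = body_ay, body_az = body_az, body_zexp = 8L,
    env_cx = 0, env_cy = -2, env_ax = 0.80 * body_ax, env_ay = 0.80 * body_ay,
    env_flat = 0.60,
    psi_zbase = dome_z + 2, psi_zapex = jit(55, 62),
    ap_frac = ap_fraction, ap_y0 = -20,
    dome_cx = jit(4, 12), dome_cy = -2, dome_z = dome_z, dome_R = jit(120, 160),
    dia_thick = jit(7, 10), dia_rad = jit(48, 58),
    lung_c = rbind(c(jit(34, 42), -4, jit(14, 20)),
                   c(-jit(34, 42), -4, jit(14, 20))),
    lung_s = rbind(c(jit(26, 32), jit(34, 40), jit(42, 48)),
                   c(jit(24, 30), jit(32, 38), jit(40, 46))),
    heart_c = c(jit(-18, -8), jit(4, 12), jit(16, 24)),
    heart_s = c(jit(20, 24), jit(22, 26), jit(27, 32)),
    rib_rho = 0.935, rib_th = 3.5, rib_z0 = jit(-52, -46), rib_dz = 18,
    rib_half = 3.2, rib_zmin = -56, rib_zmax = 58, rib_gap = 0.30,
    hu_body = 0, hu_lung = -800, hu_heart = 40, hu_dia = 40,
    hu_rib = 700, hu_nodule = 50, hu_air = -1000,
    edge_mm = edge_mm, excursion = excursion
  )
  # nodules placed inside the lung ellipsoids, away from edges
  nod <- matrix(0, 0, 4)
  if (n_nodules > 0) {
    for (i in seq_len(n_nodules)) {
      side <- 1 + (i - 1) %% 2
      fr <- if (is.null(seed)) c(0.3, -0.1, 0.2) else runif(3, -0.45, 0.45)
      r_nod <- jit(4.5, 7)
      cen <- p$lung_c[side, ] + fr * p$lung_s[side, ] * 0.9
      # keep above the diaphragm dome
      zd <- p$dome_z - ((cen[1] - p$dome_cx)^2 + (cen[2] - p$dome_cy)^2) /
        (2 * p$dome_R)
      cen[3] <- max(cen[3], zd + r_nod + 4)
      nod <- rbind(nod, c(cen, r_nod))
    }
  }
  p$nodules <- nod
  p
}

# respiratory waveform: amplitude of the pull map at each of the 10 phases,
# 1-cos over the cycle with phase 1 = end-exhale (a = 0), phase 6 = end-inhale
phase_amplitudes <- function(excursion) {
  excursion / 2 * (1 - cos(2 * pi * (0:9) / 10))
}

#' Deformable 10-phase digital thorax phantom
#'
#' Generates 10 breathing phases of a thorax (HU volumes plus anatomical
#' class labels) by evaluating an analytic reference anatomy under a
#' one-parameter family of invertible breathing maps. Because the maps are
#' invertible in closed form (per-voxel 1-D Newton solves), the DVF between
#' ANY two phases -- and between any two fractional breathing states -- is
#' exact by construction, providing a ground-truth oracle for motion-
#' compensation experiments.
#'
#' Class labels: 0 air, 1 lung, 2 lung nodule, 3 heart, 4 ribs,
#' 5 diaphragm, 6 remainder (body soft tissue). The six anatomical classes
#' tile the body; air is outside the body mask.
#'
#' @param grid a `volume_grid` the phases are rendered on
#' @param params parameter list from [thorax_params()]
#' @param seed kept for provenance in the returned object
#' @return an object of class `phantom4d` with elements `phases` (list of
#'   10 HU `ct_volume`s), `labels` (list of 10 integer arrays), `grid`,
#'   `params`, `amplitudes`
#' @export
make_thorax_phantom <- function(grid, params = thorax_params(), seed = NULL) {
  amps <- phase_amplitudes(params$excursion)
  jmin <- .cpp_thorax_jac_min(unclass(grid), params, max(amps))
  if (jmin <= 0.05)
    stop(sprintf("breathing excursion folds the deformation (min Jacobian %.3f)",
                 jmin))
  phases <- vector("list", 10)
  labels <- vector("list", 10)
  for (i in 1:10) {
    r <- .cpp_thorax_render(unclass(grid), params, amps[i])
    phases[[i]] <- volume(r$hu, grid, "HU")
    labels[[i]] <- r$labels
  }
  structure(list(phases = phases, labels = labels, grid = grid,
                 params = params, amplitudes = amps, seed = seed),
            class = "phantom4d")
}

#' @export
print.phantom4d <- function(x, ...) {
  cat(sprintf("10-phase thorax phantom on %d x %d x %d @ %.3g mm, excursion %.1f mm\n",
              x$grid$nx, x$grid$ny, x$grid$nz, x$grid$voxel_size,
              x$params$excursion))
  invisible(x)
}

#' Breathing-map amplitude at a (fractional) phase
#'
#' Real phases live in `[1, 11)` with cyclic wrap-around (phase 11 = phase
#' 1); between integer phases the amplitude is interpolated linearly.
#'
#' @param phantom a `phantom4d`
#' @param phi real phase value(s) in `[1, 11)`
#' @return amplitude(s) in mm
#' @export
amplitude_of <- function(phantom, phi) {
  if (any(phi < 1 | phi >= 11)) stop("phase must lie in [1, 11)")
  a <- c(phantom$amplitudes, phantom$amplitudes[1])  # cyclic
  lo <- floor(phi)
  frac <- phi - lo
  a[lo] + frac * (a[lo + 1] - a[lo])
}

#' Render the phantom at an arbitrary breathing state
#'
#' @param phantom a `phantom4d`
#' @param phi real phase in `[1, 11)`
#' @param with_labels also return the class label map
#' @return a `ct_volume` (HU), or a list `(volume, labels)` if
#'   `with_labels` is `TRUE`
#' @export
phantom_state <- function(phantom, phi, with_labels = FALSE) {
  a <- amplitude_of(phantom, phi)
  r <- .cpp_thorax_render(unclass(phantom$grid), phantom$params, a)
  v <- volume(r$hu, phantom$grid, "HU")
  if (with_labels) list(volume = v, labels = r$labels) else v
}

#' Exact DVF between two breathing states of a phantom
#'
#' Returns the pull-convention field `u` with
#' `warp(state_src, u) == state_tgt` (exact up to interpolation), computed
#' in closed form from the breathing parameterization. Phases may be
#' integer (1..10) or fractional.
#'
#' @param phantom a `phantom4d`
#' @param i source phase (real, in `[1, 11)`)
#' @param n target phase (real, in `[1, 11)`)
#' @return a `dvf` on the phantom grid
#' @export
dvf_between <- function(phantom, i, n) {
  a_src <- amplitude_of(phantom, i)
  a_tgt <- amplitude_of(phantom, n)
  u <- .cpp_thorax_dvf(unclass(phantom$grid), phantom$params, a_src, a_tgt)
  dvf(u, phantom$grid, source = i, target = n)
}
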