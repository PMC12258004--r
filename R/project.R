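#' Cone-beam forward projection
#'
#' Ray-driven line integrals with trilinear sampling at a configurable step
#' (default half the voxel size). The operator is linear in the volume.
#'
#' @param vol a `ct_volume` in attenuation units (`"mu"`)
#' @param geom a `cone_beam_geometry`
#' @param view_indices 1-based view indices to project (default: all views)
#' @param step ray sampling step, mm
#' @return a `projection_set` whose geometry keeps only the selected angles
#' @export
forward_project <- function(vol, geom, view_indices = seq_len(geom$n_views),
                            step = vol$grid$voxel_size / 2) {
  if (vol$unit != "mu")
    stop("forward_project expects attenuation units; see convert_unit()")
  if (any(view_indices < 1 | view_indices > geom$n_views))
    stop("view index out of range")
  frames <- .cpp_forward_project(vol$values, unclass(vol$grid), unclass(geom),
                                 as.integer(view_indices) - 1L, step)
  sub <- geom
  sub$angles <- geom$angles[view_indices]
  sub$n_views <- length(view_indices)
  projection_set(frames, sub)
}

# frequency response of the band-limited ramp (Ramachandran-Lakshminarayanan)
# kernel at sampling pitch tau, with a smooth apodization window
ramp_response <- function(L, tau, window = c("cosine", "hann", "ramlak")) {
  window <- match.arg(window)
  h <- numeric(L)
  k <- c(0:(L / 2), -(L / 2 - 1):-1)  # circular sample offsets
  h[1] <- 1 / (4 * tau^2)
  odd <- which(k %% 2 != 0)
  h[odd] <- -1 / (pi^2 * k[odd]^2 * tau^2)
  H <- Re(stats::fft(h))
  m <- c(0:(L / 2), (L / 2 - 1):1)  # frequency bin magnitude
  w <- switch(window,
              ramlak = rep(1, L),
              cosine = cos(pi / 2 * m / (L / 2)),
              hann = 0.5 * (1 + cos(pi * m / (L / 2))))
  H * w
}

# shifted-detector redundancy weight on isocenter-scaled detector coordinate
# ubar; raised-sine feathering of half-width W around u = 0 so that
# w(u) + w(-u) = 1 for doubly measured rays
redundancy_weight <- function(ubar, W) {
  w <- 0.5 * (1 + sin(pi * ubar / (2 * W)))
  w[ubar <= -W] <- 0
  w[ubar >= W] <- 1
  w
}

# cosine pre-weighting + redundancy weighting + 1-D ramp filtering along u,
# for the frames of a projection set (all in isocenter-scaled coordinates)
filter_frames <- function(frames, geom, window = "cosine",
                          feather_fraction = 0.1) {
  d <- dim(frames)
  n_u <- d[1]; n_v <- d[2]; n_f <- d[3]
  mag <- geom$sdd / geom$sid
  tau <- geom$pixel_u / mag
  ubar <- ((seq_len(n_u) - 1) - (n_u - 1) / 2) * tau + geom$detector_offset_u / mag
  vbar <- ((seq_len(n_v) - 1) - (n_v - 1) / 2) * geom$pixel_v / mag
  cosw <- geom$sid / sqrt(geom$sid^2 + outer(ubar^2, vbar^2, "+"))
  det_w <- (n_u - 1) * tau
  overlap <- min(abs(min(ubar)), max(ubar))
  W <- min(feather_fraction * det_w, overlap)
  if (W <= 0) W <- det_w / 2  # centered detector: constant 1/2 everywhere
  red <- redundancy_weight(ubar, W)
  L <- 2^ceiling(log2(2 * n_u))
  H <- ramp_response(L, tau, window)
  out <- array(0, d)
  for (k in seq_len(n_f)) {
    fr <- frames[, , k] * cosw * red
    pad <- matrix(0, L, n_v)
    pad[seq_len(n_u), ] <- fr
    q <- Re(stats::mvfft(stats::mvfft(pad) * H, inverse = TRUE)) / L * tau
    out[, , k] <- q[seq_len(n_u), ]
  }
  out
}

#' Single-angle filtered backprojection (SAR)
#'
#' The i-th view's FDK contribution: cosine pre-weighting, shifted-detector
#' redundancy weighting, 1-D ramp filtering along u, and distance-weighted
#' voxel-driven backprojection with the view's angular weight. Summing the
#' SARs of all views reproduces [fdk_reconstruct()] exactly.
#'
#' @param proj a `projection_set`
#' @param i 1-based view index
#' @param grid reconstruction `volume_grid`
#' @param window ramp apodization: `"cosine"` (default), `"hann"`, `"ramlak"`
#' @param feather_fraction redundancy feathering half-width as a fraction of
#'   the detector width
#' @param view_weights optional per-view angular weights (radians); default
#'   Voronoi weights of the set's angles
#' @return a `ct_volume` in attenuation units
#' @export
backproject_single_filtered <- function(proj, i, grid, window = "cosine",
                                        feather_fraction = 0.1,
                                        view_weights = NULL) {
  geom <- proj$geometry
  if (i < 1 || i > geom$n_views) stop("view index out of range")
  if (is.null(view_weights)) view_weights <- angular_weights(geom$angles)
  filt <- filter_frames(proj$frames[, , i, drop = FALSE], geom, window,
                        feather_fraction)
  vals <- .cpp_backproject_fdk(filt, unclass(grid), unclass(geom),
                               as.integer(i) - 1L, view_weights[i])
  volume(vals, grid, "mu")
}

#' Single-angle unfiltered backprojection (adjoint)
#'
#' The exact adjoint of [forward_project()] for one view (same ray marching,
#' scatter instead of gather): `<X v, p> == <v, X^T p>` to floating
#' precision. Used by the SART-type modified-SAR update.
#'
#' @inheritParams backproject_single_filtered
#' @param step ray sampling step, mm
#' @return a `ct_volume` in attenuation units
#' @export
backproject_single_unfiltered <- function(proj, i, grid,
                                          step = grid$voxel_size / 2) {
  geom <- proj$geometry
  if (i < 1 || i > geom$n_views) stop("view index out of range")
  vals <- .cpp_backproject_adjoint(proj$frames[, , i, drop = FALSE],
                                   unclass(grid), unclass(geom),
                                   as.integer(i) - 1L, step)
  volume(vals, grid, "mu")
}

#' FDK reconstruction
#'
#' Feldkamp-Davis-Kress filtered backprojection for a full-rotation
#' circular cone-beam scan, with shifted-detector redundancy weighting.
#' Equals the sum of all single-angle reconstructions by construction.
#'
#' @inheritParams backproject_single_filtered
#' @param view_indices subset of views to reconstruct from (default: all)
#' @return a `ct_volume` in attenuation units
#' @export
fdk_reconstruct <- function(proj, grid, window = "cosine",
                            feather_fraction = 0.1,
                            view_indices = seq_len(proj$geometry$n_views),
                            view_weights = NULL) {
  geom <- proj$geometry
  arc <- diff(range(geom$angles %% (2 * pi)))
  if (geom$detector_offset_u != 0 && length(geom$angles) > 2) {
    # a shifted detector needs the full circle for complete data
    gaps <- diff(sort(c(geom$angles %% (2 * pi),
                        min(geom$angles %% (2 * pi)) + 2 * pi)))
    if (max(gaps) > pi / 2)
      stop("shifted-detector scan does not cover the full rotation")
  }
  if (is.null(view_weights))
    view_weights <- angular_weights(geom$angles)[view_indices]
  filt <- filter_frames(proj$frames[, , view_indices, drop = FALSE], geom,
                        window, feather_fraction)
  vals <- .cpp_backproject_fdk(filt, unclass(grid), unclass(geom),
                               as.integer(view_indices) - 1L, view_weights)
  volume(vals, grid, "mu")
}
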