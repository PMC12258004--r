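#' Simulate a 4D cone-beam CT scan of a breathing thorax phantom
#'
#' For every view the phantom is evaluated at the view's (fractional)
#' breathing state and a single cone-beam projection of that state is
#' computed, emulating the continuous transition between motion states of
#' a real scan. The returned record carries exact per-view oracles: the
#' ground-truth state volume of any view and the exact DVF between any two
#' views (from the phantom's closed-form breathing parameterization).
#'
#' @param phantom a `phantom4d`
#' @param signal a `phase_signal` with one phase per view
#' @param geom a `cone_beam_geometry` with `n_views == signal$n_views`
#' @param noise_photons optional incident photon count per detector pixel;
#'   when given, Poisson noise is applied to the transmitted intensities
#' @param step ray sampling step, mm
#' @param seed seed for the noise draw (recorded for provenance)
#' @return an object of class `scan_record`
#' @export
simulate_scan <- function(phantom, signal, geom, noise_photons = NULL,
                          step = phantom$grid$voxel_size / 2, seed = 1) {
  if (signal$n_views != geom$n_views)
    stop("signal length must equal the number of views")
  frames <- array(0, c(geom$n_u, geom$n_v, geom$n_views))
  amps <- amplitude_of(phantom, signal$phi)
  # group identical amplitudes (static or integer-phase signals) to avoid
  # re-rendering
  grp <- split(seq_len(geom$n_views), amps)
  for (g in grp) {
    st <- convert_unit(phantom_state(phantom, signal$phi[g[1]]), "mu")
    p <- forward_project(st, geom, view_indices = g, step = step)
    frames[, , g] <- p$frames
  }
  if (!is.null(noise_photons)) {
    set.seed(seed)
    counts <- stats::rpois(length(frames), noise_photons * exp(-frames))
    counts[counts < 1] <- 1
    frames <- array(-log(counts / noise_photons), dim(frames))
  }
  structure(list(projections = projection_set(frames, geom),
                 signal = signal, phantom = phantom, geometry = geom,
                 amplitudes = amps, noise_photons = noise_photons,
                 seed = seed),
            class = "scan_record")
}

#' @export
print.scan_record <- function(x, ...) {
  cat(sprintf("scan record: %d views, phase range [%.2f, %.2f]%s\n",
              x$geometry$n_views, min(x$signal$phi), max(x$signal$phi),
              if (is.null(x$noise_photons)) ", noiseless"
              else sprintf(", %g photons", x$noise_photons)))
  invisible(x)
}

#' Ground-truth state volume of a view
#' @param scan a `scan_record`
#' @param n view index
#' @param with_labels also return the class label map
#' @return a `ct_volume` in HU (or a list with labels)
#' @export
scan_gt_volume <- function(scan, n, with_labels = FALSE) {
  phantom_state(scan$phantom, scan$signal$phi[n], with_labels = with_labels)
}

#' Exact ground-truth DVF between two views of a scan
#'
#' `warp(scan_gt_volume(scan, i), scan_gt_dvf(scan, i, n))` reproduces
#' `scan_gt_volume(scan, n)` up to interpolation error.
#'
#' @param scan a `scan_record`
#' @param i source view index
#' @param n target view index
#' @return a `dvf`
#' @export
scan_gt_dvf <- function(scan, i, n) {
  dvf_between(scan$phantom, scan$signal$phi[i], scan$signal$phi[n])
}

#' Simulate the periodically scaled toy scan
#'
#' Every view projects the cylinder phantom scaled by
#' `s(i) = 1 + amplitude*sin(freq*i)` (i = 0 for the first view), the toy
#' motion law that demonstrates the residual-streak mechanism of warped-SAR
#' reconstruction.
#'
#' @param grid rendering `volume_grid`
#' @param geom a `cone_beam_geometry`
#' @param amplitude,freq parameters of [toy_transform()]
#' @param inserts insert list for [make_toy_phantom()]
#' @param radius cylinder radius, mm
#' @param edge_mm edge blend width passed to [make_toy_phantom()]
#' @param step ray sampling step, mm
#' @return a list of class `toy_scan` with `projections`, `scales`, `grid`,
#'   and the phantom spec
#' @export
simulate_toy_scan <- function(grid, geom, amplitude = 0.1, freq = 0.15,
                              inserts = toy_inserts(), radius = 60,
                              edge_mm = 2, step = grid$voxel_size / 2) {
  scales <- vapply(seq_len(geom$n_views) - 1,
                   function(i) toy_transform(i, amplitude, freq)$s_xy, 0)
  frames <- array(0, c(geom$n_u, geom$n_v, geom$n_views))
  for (i in seq_len(geom$n_views)) {
    st <- convert_unit(make_toy_phantom(grid, inserts, radius,
                                        scale = scales[i],
                                        edge_mm = edge_mm), "mu")
    p <- forward_project(st, geom, view_indices = i, step = step)
    frames[, , i] <- p$frames
  }
  structure(list(projections = projection_set(frames, geom),
                 scales = scales, grid = grid, inserts = inserts,
                 radius = radius, amplitude = amplitude, freq = freq,
                 edge_mm = edge_mm),
            class = "toy_scan")
}

#' Persist / load a scan record as a directory of plain files
#'
#' Projections and label maps as NIfTI, geometry as JSON, signal as CSV,
#' phantom parameters as YAML.
#'
#' @param scan a `scan_record`
#' @param dir output directory
#' @return `read_scan_record` returns the reconstructed pieces (projection
#'   set, signal, geometry, parameters); the phantom oracles require
#'   rebuilding the phantom from the stored parameters
#' @export
write_scan_record <- function(scan, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img <- RNifti::asNifti(scan$projections$frames)
  RNifti::writeNifti(img, file.path(dir, "projections.nii.gz"))
  write_geometry(scan$geometry, file.path(dir, "geometry.json"))
  write_signal(scan$signal, file.path(dir, "signal.csv"))
  p <- scan$phantom$params
  p$nodules <- apply(p$nodules, 1, as.list)
  p$lung_c <- apply(p$lung_c, 1, as.list)
  p$lung_s <- apply(p$lung_s, 1, as.list)
  yaml::write_yaml(list(params = p, seed = scan$seed,
                        grid = unclass(scan$phantom$grid),
                        noise_photons = scan$noise_photons),
                   file.path(dir, "phantom.yaml"))
  leg <- list("0" = "air", "1" = "lung", "2" = "lung_nodule", "3" = "heart",
              "4" = "ribs", "5" = "diaphragm", "6" = "remainder")
  jsonlite::write_json(leg, file.path(dir, "labels_legend.json"),
                       auto_unbox = TRUE)
  lab <- RNifti::asNifti(array(as.integer(scan$phantom$labels[[1]]),
                               dim(scan$phantom$labels[[1]])))
  RNifti::writeNifti(lab, file.path(dir, "labels_phase1.nii.gz"))
  invisible(dir)
}

#' @rdname write_scan_record
#' @export
read_scan_record <- function(dir) {
  geom <- read_geometry(file.path(dir, "geometry.json"))
  frames <- array(as.numeric(RNifti::readNifti(
    file.path(dir, "projections.nii.gz"))),
    c(geom$n_u, geom$n_v, geom$n_views))
  sig <- read_signal(file.path(dir, "signal.csv"))
  meta <- yaml::read_yaml(file.path(dir, "phantom.yaml"))
  list(projections = projection_set(frames, geom), signal = sig,
       geometry = geom, params = meta$params, grid = meta$grid,
       seed = meta$seed)
}
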