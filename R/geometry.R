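#' Cone-beam scan geometry
#'
#' Describes a circular cone-beam trajectory with a flat detector, optionally
#' operated in shifted-detector mode (laterally off-centred detector, which
#' doubles the lateral field of measurement over a full rotation at the cost
#' of requiring redundancy weighting during filtered backprojection).
#'
#' Conventions: world coordinates in mm with the isocenter at the origin and
#' z the rotation axis; the view angle is the source azimuth, counter-
#' clockwise from +x; detector coordinate u increases with azimuth and is
#' measured from the principal ray, so pixel iu sits at
#' `(iu - (n_u-1)/2) * pixel_u + detector_offset_u` (1-based callers pass
#' view indices 1..n_views).
#'
#' @param sid source-to-isocenter distance, mm
#' @param sdd source-to-detector distance, mm (must exceed `sid`)
#' @param n_u,n_v detector columns / rows
#' @param pixel_u,pixel_v detector pixel pitch, mm
#' @param detector_offset_u lateral detector shift, mm
#' @param n_views number of views; ignored when `angles` is given
#' @param angles gantry angles in radians, one per view; default: `n_views`
#'   uniform steps over a full rotation
#' @return an object of class `cone_beam_geometry`
#' @export
cone_beam_geometry <- function(sid, sdd, n_u, n_v, pixel_u, pixel_v,
                               detector_offset_u = 0, n_views = NULL,
                               angles = NULL) {
  if (!(sdd > sid && sid > 0)) stop("need sdd > sid > 0")
  if (pixel_u <= 0 || pixel_v <= 0) stop("pixel pitches must be positive")
  if (is.null(angles)) {
    if (is.null(n_views)) stop("give either n_views or angles")
    angles <- 2 * pi * (seq_len(n_views) - 1) / n_views
  }
  n_views <- length(angles)
  if (n_views < 1) stop("need at least one view")
  # lateral half-width must still cover the principal ray (u = 0)
  half_w <- (n_u - 1) / 2 * pixel_u
  if (abs(detector_offset_u) >= half_w)
    stop("detector offset places the principal ray off the detector")
  structure(list(sid = sid, sdd = sdd, n_u = as.integer(n_u),
                 n_v = as.integer(n_v), pixel_u = pixel_u, pixel_v = pixel_v,
                 detector_offset_u = detector_offset_u,
                 angles = as.numeric(angles), n_views = as.integer(n_views)),
            class = "cone_beam_geometry")
}

#' @export
print.cone_beam_geometry <- function(x, ...) {
  cat(sprintf(
    "cone-beam geometry: SID %.0f / SDD %.0f mm, %d x %d detector (%.3g x %.3g mm px),\n  offset_u %.1f mm, %d views over %.1f deg\n",
    x$sid, x$sdd, x$n_u, x$n_v, x$pixel_u, x$pixel_v, x$detector_offset_u,
    x$n_views, diff(range(x$angles)) * 180 / pi * x$n_views / (x$n_views - 1)))
  invisible(x)
}

#' Varian TrueBeam kV geometry preset
#'
#' Full-scale clinical geometry: SID 1000 mm, SDD 1500 mm, 1024 x 768
#' detector with 0.388 mm pixels (2x2 binning), detector laterally
#' off-centred by 160 mm, full rotation.
#'
#' @param n_views number of views over the full rotation (clinical scans
#'   acquire roughly 660-840; the simulation protocol uses 657)
#' @return a `cone_beam_geometry`
#' @export
truebeam_geometry <- function(n_views = 657) {
  cone_beam_geometry(sid = 1000, sdd = 1500, n_u = 1024, n_v = 768,
                     pixel_u = 0.388, pixel_v = 0.388,
                     detector_offset_u = 160, n_views = n_views)
}

#' Scaled-down shifted-detector geometry for desk-scale experiments
#'
#' Same SID/SDD ratio and shifted-detector mode as the clinical preset but
#' with a coarse detector, sized so that thorax-scale phantoms on 64-128
#' voxel grids are fully measured.
#'
#' @param n_views number of views over the full rotation
#' @param n_u,n_v detector columns / rows
#' @param pixel_mm detector pixel pitch, mm
#' @param detector_offset_u lateral shift, mm
#' @return a `cone_beam_geometry`
#' @export
scaled_geometry <- function(n_views = 164, n_u = 128, n_v = 96,
                            pixel_mm = 2.6, detector_offset_u = 60) {
  cone_beam_geometry(sid = 1000, sdd = 1500, n_u = n_u, n_v = n_v,
                     pixel_u = pixel_mm, pixel_v = pixel_mm,
                     detector_offset_u = detector_offset_u, n_views = n_views)
}

#' Per-view angular integration weights
#'
#' Voronoi weights on the circle: each view is weighted by half the angular
#' gap to its two neighbours, so non-uniform subsets (e.g. after gating)
#' stay quantitatively calibrated. For uniform full-circle sampling this
#' reduces to `2*pi/n`.
#'
#' @param angles view angles, radians (any order)
#' @return weights in radians, summing to `2*pi`, in the input order
#' @export
angular_weights <- function(angles) {
  n <- length(angles)
  if (n == 1) return(2 * pi)
  a <- angles %% (2 * pi)
  ord <- order(a)
  as <- a[ord]
  gaps <- diff(c(as, as[1] + 2 * pi))  # gap following each sorted angle
  prev_gaps <- c(gaps[n], gaps[-n])
  w_sorted <- (gaps + prev_gaps) / 2
  w <- numeric(n)
  w[ord] <- w_sorted
  w
}

#' Read / write scan geometry as JSON
#'
#' Keys mirror the fields of [cone_beam_geometry()] (mm and radians).
#'
#' @param geom a `cone_beam_geometry`
#' @param path file path
#' @return `read_geometry` returns a `cone_beam_geometry`
#' @export
write_geometry <- function(geom, path) {
  jsonlite::write_json(unclass(geom), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  cone_beam_geometry(sid = g$sid, sdd = g$sdd, n_u = g$n_u, n_v = g$n_v,
                     pixel_u = g$pixel_u, pixel_v = g$pixel_v,
                     detector_offset_u = g$detector_offset_u,
                     angles = g$angles)
}
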