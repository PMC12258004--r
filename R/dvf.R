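#' Displacement vector field (DVF)
#'
#' Backward (pull) convention: a DVF `u` defined on the TARGET state's grid
#' deforms a source-state volume via `out(r) = vol(r + u(r))`. Components
#' are ordered (x, y, z), units mm. A zero field is the identity transform.
#'
#' @param u numeric array `(nx, ny, nz, 3)`, displacements in mm
#' @param grid the target state's `volume_grid`
#' @param source,target free-form state identifiers (bookkeeping only)
#' @return an object of class `dvf`
#' @export
dvf <- function(u, grid, source = NA, target = NA) {
  u <- as.array(u)
  if (!identical(dim(u), c(grid$nx, grid$ny, grid$nz, 3L)))
    stop("DVF shape must be (nx, ny, nz, 3)")
  if (!all(is.finite(u))) stop("DVF contains non-finite values")
  structure(list(u = u, grid = grid, source = source, target = target),
            class = "dvf")
}

#' Zero DVF on a grid
#' @param grid a `volume_grid`
#' @return a `dvf` representing the identity transform
#' @export
zero_dvf <- function(grid) {
  dvf(array(0, c(grid$nx, grid$ny, grid$nz, 3L)), grid)
}

#' @export
print.dvf <- function(x, ...) {
  mags <- sqrt(x$u[, , , 1]^2 + x$u[, , , 2]^2 + x$u[, , , 3]^2)
  cat(sprintf("DVF %d x %d x %d (%s -> %s), |u| mean %.3g / max %.3g mm\n",
              x$grid$nx, x$grid$ny, x$grid$nz, x$source, x$target,
              mean(mags), max(mags)))
  invisible(x)
}

#' Warp a volume with a DVF (spatial transformer)
#'
#' `out(r) = vol(r + u(r))` with trilinear interpolation and edge-clamped
#' (replicate) out-of-range sampling. Linear in the volume.
#'
#' @param vol a `ct_volume` on the same grid as the DVF
#' @param d a `dvf`
#' @return a warped `ct_volume` in the same unit
#' @export
warp <- function(vol, d) {
  if (!grids_equal(vol$grid, d$grid)) stop("volume and DVF grids differ")
  vals <- .cpp_warp(vol$values, d$u, vol$grid$voxel_size)
  volume(vals, vol$grid, vol$unit)
}

#' Approximate inverse of a DVF
#'
#' Fixed-point iteration `u_hat(r) = -u(r + u_hat(r))` until the maximum
#' update falls below `tol` (mm) or `max_iter` iterations. Valid in the
#' diffeomorphic regime (displacements small compared to field curvature).
#' Non-convergence is flagged in the returned object, not raised.
#'
#' @param d a `dvf`
#' @param tol convergence tolerance on the update, mm
#' @param max_iter maximum number of fixed-point iterations
#' @return a `dvf` with attributes `converged` and `residual`
#' @export
invert_dvf <- function(d, tol = 0.01, max_iter = 50) {
  res <- .cpp_invert_dvf(d$u, d$grid$voxel_size, tol, as.integer(max_iter))
  out <- dvf(res$dvf, d$grid, source = d$target, target = d$source)
  attr(out, "converged") <- res$converged
  attr(out, "residual") <- res$residual
  if (!res$converged)
    warning(sprintf("DVF inversion did not converge (residual %.3g mm)",
                    res$residual))
  out
}

#' Composition residual of two DVFs
#'
#' Returns `u(r + u_hat(r)) + u_hat(r)`, which is zero when `u_hat` is the
#' exact inverse of `u`.
#'
#' @param d a `dvf`
#' @param d_inv a candidate inverse `dvf` on the same grid
#' @return array `(nx, ny, nz, 3)` of residual displacements, mm
#' @export
compose_residual <- function(d, d_inv) {
  if (!grids_equal(d$grid, d_inv$grid)) stop("grids differ")
  .cpp_compose_dvf(d$u, d_inv$u, d$grid$voxel_size)
}

#' In-plane affine scaling (toy motion model)
#'
#' The view-dependent axial scaling `s(i) = 1 + amplitude*sin(freq*i)`
#' applied to a phantom: the motion state at view `i` is the object scaled
#' by `s(i)` in the (x, y) plane about `center`, z unscaled.
#'
#' @param s_xy in-plane scale factor (> 0)
#' @param center length-2 fixed point, mm
#' @return an object of class `affine_scaling`
#' @export
affine_scaling <- function(s_xy, center = c(0, 0)) {
  if (s_xy <= 0) stop("s_xy must be positive")
  structure(list(s_xy = s_xy, center = as.numeric(center)),
            class = "affine_scaling")
}

#' @describeIn affine_scaling the periodic toy motion law
#' @param i view index (the first view of a scan has `i = 0`)
#' @param amplitude scaling amplitude (must be < 1 for invertibility)
#' @param freq per-view angular frequency of the scaling oscillation
#' @export
toy_transform <- function(i, amplitude = 0.1, freq = 0.15) {
  if (amplitude >= 1) stop("amplitude >= 1 gives a non-invertible scaling")
  affine_scaling(1 + amplitude * sin(freq * i))
}

#' Exact DVF between two scaling states
#'
#' For motion states `f_s(r) = f_D(S_s^{-1} r)` (object scaled by `s`), the
#' pull-convention field that warps the source state into the target state
#' is `u(r) = (s_src/s_tgt - 1) * (x - cx, y - cy, 0)`.
#'
#' @param src,tgt `affine_scaling` objects sharing a center
#' @param grid target `volume_grid`
#' @return a `dvf`
#' @export
scaling_dvf <- function(src, tgt, grid) {
  if (!isTRUE(all.equal(src$center, tgt$center)))
    stop("scalings must share a center")
  fac <- src$s_xy / tgt$s_xy - 1
  co <- grid_coords(grid)
  u <- array(0, c(grid$nx, grid$ny, grid$nz, 3L))
  u[, , , 1] <- fac * (co$x - src$center[1])
  u[, , , 2] <- rep(fac * (co$y - src$center[2]), each = grid$nx)
  dvf(u, grid, source = sprintf("s=%.4f", src$s_xy),
      target = sprintf("s=%.4f", tgt$s_xy))
}

#' Fractional inter-phase state interpolation
#'
#' Given a phase volume and the DVF to the next phase, produces the
#' intermediate state at fraction `frac` of the transition. The default
#' (and recommended) reading scales the displacement: `warp(vol, frac*u)`.
#' The literal-intensity alternative multiplies the fully warped volume by
#' `frac`, which fades intensities and is retained only for comparison.
#'
#' @param phase_vol a `ct_volume` at integer phase
#' @param dvf_to_next the `dvf` mapping this phase to the next one
#' @param frac fraction in `[0, 1)`
#' @param mode `"displacement"` (default) or `"intensity"`
#' @return a `ct_volume`
#' @export
interpolate_phase_state <- function(phase_vol, dvf_to_next, frac,
                                    mode = c("displacement", "intensity")) {
  mode <- match.arg(mode)
  if (frac < 0 || frac >= 1) stop("frac must lie in [0, 1)")
  if (mode == "displacement") {
    if (frac == 0) return(phase_vol)
    d <- dvf(dvf_to_next$u * frac, dvf_to_next$grid,
             source = dvf_to_next$source, target = "interpolated")
    warp(phase_vol, d)
  } else {
    volume(frac * warp(phase_vol, dvf_to_next)$values, phase_vol$grid,
           phase_vol$unit)
  }
}

#' Write / read a DVF as 4D NIfTI (last axis = component, mm)
#' @param d a `dvf`
#' @param path output path
#' @return `read_dvf` returns a `dvf`
#' @export
write_dvf <- function(d, path) {
  img <- RNifti::asNifti(d$u)
  RNifti::pixdim(img) <- c(rep(d$grid$voxel_size, 3), 1)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(source = d$source, target = d$target,
                            origin = d$grid$origin),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dvf
#' @export
read_dvf <- function(path) {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1]
  u <- array(as.numeric(img), dim = dim(img))
  src <- NA; tgt <- NA; origin <- "centered"
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    src <- meta$source; tgt <- meta$target; origin <- meta$origin
  }
  g <- volume_grid(dim(u)[1], dim(u)[2], dim(u)[3], vs, origin)
  dvf(u, g, src, tgt)
}
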