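#' Volume grid
#'
#' A mm-calibrated isotropic 3D voxel grid. The origin is the world
#' coordinate of the center of voxel (1,1,1); by default the grid is
#' centred on the isocenter.
#'
#' @param nx,ny,nz voxel counts
#' @param voxel_size isotropic voxel edge length, mm
#' @param origin numeric length-3 world coordinate (mm) of the first voxel
#'   center, or `"centered"`
#' @return an object of class `volume_grid`
#' @export
volume_grid <- function(nx, ny, nz, voxel_size, origin = "centered") {
  if (any(c(nx, ny, nz) < 1)) stop("voxel counts must be >= 1")
  if (voxel_size <= 0) stop("voxel_size must be positive")
  if (identical(origin, "centered"))
    origin <- -c(nx - 1, ny - 1, nz - 1) / 2 * voxel_size
  structure(list(nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
                 voxel_size = voxel_size, origin = as.numeric(origin)),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume grid: %d x %d x %d @ %.3g mm\n", x$nx, x$ny, x$nz,
              x$voxel_size))
  invisible(x)
}

grids_equal <- function(a, b) {
  a$nx == b$nx && a$ny == b$ny && a$nz == b$nz &&
    isTRUE(all.equal(a$voxel_size, b$voxel_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' World coordinates of all voxel centers along each axis
#' @param grid a `volume_grid`
#' @return list with numeric vectors `x`, `y`, `z` (mm)
#' @export
grid_coords <- function(grid) {
  list(x = grid$origin[1] + (seq_len(grid$nx) - 1) * grid$voxel_size,
       y = grid$origin[2] + (seq_len(grid$ny) - 1) * grid$voxel_size,
       z = grid$origin[3] + (seq_len(grid$nz) - 1) * grid$voxel_size)
}

#' Scalar volume on a grid
#'
#' @param values numeric array with dim `(nx, ny, nz)`; finite
#' @param grid a `volume_grid`
#' @param unit `"HU"` or `"mu"` (attenuation, 1/mm)
#' @return an object of class `ct_volume`
#' @export
volume <- function(values, grid, unit = c("HU", "mu")) {
  unit <- match.arg(unit)
  values <- as.array(values)
  if (!identical(dim(values), c(grid$nx, grid$ny, grid$nz)))
    stop("values shape does not match grid")
  if (!all(is.finite(values))) stop("volume contains non-finite values")
  structure(list(values = values, grid = grid, unit = unit),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("volume %d x %d x %d @ %.3g mm [%s], range %.4g .. %.4g\n",
              x$grid$nx, x$grid$ny, x$grid$nz, x$grid$voxel_size, x$unit,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Convert a volume between HU and attenuation units
#' @param vol a `ct_volume`
#' @param unit target unit, `"HU"` or `"mu"`
#' @return a `ct_volume` in the requested unit
#' @export
convert_unit <- function(vol, unit = c("HU", "mu")) {
  unit <- match.arg(unit)
  if (vol$unit == unit) return(vol)
  v <- if (unit == "mu") hu_to_mu(vol$values) else mu_to_hu(vol$values)
  volume(v, vol$grid, unit)
}

#' Projection set
#'
#' Per-view 2D line-integral images (dimensionless) bound to a geometry.
#' Frames are stored as an `(n_u, n_v, n_views)` array.
#'
#' @param frames numeric array `(n_u, n_v, n_views)`
#' @param geometry a `cone_beam_geometry`
#' @return an object of class `projection_set`
#' @export
projection_set <- function(frames, geometry) {
  frames <- as.array(frames)
  d <- dim(frames)
  if (length(d) == 2) { dim(frames) <- c(d, 1); d <- dim(frames) }
  if (d[1] != geometry$n_u || d[2] != geometry$n_v)
    stop("frame shape does not match detector")
  if (d[3] != geometry$n_views)
    stop("frame count does not match n_views")
  if (!all(is.finite(frames))) stop("projections contain non-finite values")
  structure(list(frames = frames, geometry = geometry),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  cat(sprintf("projection set: %d views of %d x %d\n",
              x$geometry$n_views, x$geometry$n_u, x$geometry$n_v))
  invisible(x)
}

#' Write / read a volume as NIfTI
#'
#' Voxel size is carried in the NIfTI header; the unit tag is appended to
#' the file name's sidecar JSON.
#'
#' @param vol a `ct_volume`
#' @param path output path (`.nii` or `.nii.gz`)
#' @return `read_volume` returns a `ct_volume`
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- rep(vol$grid$voxel_size, 3)
  RNifti::writeNifti(img, path)
  side <- paste0(path, ".json")
  jsonlite::write_json(list(unit = vol$unit, origin = vol$grid$origin),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @param unit unit tag used when no sidecar JSON is present
#' @export
read_volume <- function(path, unit = "HU") {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1]
  vals <- array(as.numeric(img), dim = dim(img))
  origin <- "centered"
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    unit <- meta$unit
    origin <- meta$origin
  }
  g <- volume_grid(dim(vals)[1], dim(vals)[2], dim(vals)[3], vs, origin)
  volume(vals, g, unit)
}
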