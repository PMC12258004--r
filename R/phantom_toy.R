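#' Toy cylinder phantom with high-contrast inserts
#'
#' Water-equivalent cylinder (0 HU, axis parallel to z) in air (-1000 HU)
#' with optional high-contrast inserts (default +1000 HU discs or bars).
#' Rendered analytically, so a scaled motion state can be produced exactly
#' by evaluating at `r/s`.
#'
#' @param grid a `volume_grid`
#' @param inserts list of insert specs; each a list with `type`
#'   (`"disc"` or `"bar"`), `center` (x, y mm), size (`radius` for discs,
#'   `half_size` length-2 for bars), and optional `hu` (default +1000)
#' @param radius cylinder radius, mm
#' @param scale in-plane scale factor of the motion state (object scaled
#'   by `scale` about the cylinder axis)
#' @param edge_mm smooth edge blend width, mm (reduces aliasing)
#' @return a `ct_volume` in HU
#' @export
make_toy_phantom <- function(grid, inserts = toy_inserts(), radius = 60,
                             scale = 1, edge_mm = 2) {
  co <- grid_coords(grid)
  # evaluate the reference object at r / scale
  x <- co$x / scale
  y <- co$y / scale
  for (ins in inserts) {
    r_ins <- sqrt(sum(ins$center^2)) +
      if (ins$type == "disc") ins$radius else max(ins$half_size)
    if (r_ins > radius) stop("insert extends outside the cylinder")
  }
  blend <- function(d) pmin(pmax(0.5 - d / edge_mm, 0), 1)
  rad2 <- outer(x^2, y^2, "+")
  a_cyl <- blend(sqrt(rad2) - radius)
  hu_xy <- -1000 + a_cyl * (0 - (-1000))
  for (ins in inserts) {
    hu_i <- if (is.null(ins$hu)) 1000 else ins$hu
    if (ins$type == "disc") {
      d <- sqrt(outer((x - ins$center[1])^2, (y - ins$center[2])^2, "+")) -
        ins$radius
    } else {
      dx <- abs(x - ins$center[1]) - ins$half_size[1]
      dy <- abs(y - ins$center[2]) - ins$half_size[2]
      d <- outer(dx, dy, pmax)
    }
    a <- blend(d)
    hu_xy <- hu_xy + a * (hu_i - hu_xy)
  }
  vals <- array(hu_xy, c(grid$nx, grid$ny, grid$nz))
  volume(vals, grid, "HU")
}

#' Default insert layout for the toy phantom
#'
#' Three discs of different radii and one bar, all +1000 HU, arranged
#' asymmetrically so scaling is measurable in every direction.
#' @return a list of insert specs for [make_toy_phantom()]
#' @export
toy_inserts <- function() {
  list(list(type = "disc", center = c(25, 0), radius = 8),
       list(type = "disc", center = c(-20, 18), radius = 5),
       list(type = "disc", center = c(-8, -24), radius = 11),
       list(type = "bar", center = c(8, 22), half_size = c(18, 3)))
}
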