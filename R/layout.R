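#' Cage layout geometry
#'
#' Describes the overhead-camera geometry of the homecage: the pixel
#' positions of the two object windows on the left and right walls, the
#' corridor entry points, the arena bounds and the pixel-per-centimetre
#' calibration. Coordinates are image pixels, origin top-left, y increasing
#' downward.
#'
#' Defaults correspond to a 39 x 32 cm cage imaged at 5 px/cm with the two
#' object windows midway along the left and right walls and the corridor
#' entries at the bottom corners.
#'
#' @param arena_w_px,arena_h_px arena bounds in pixels.
#' @param px_per_cm calibration (> 0).
#' @param object_left,object_right object-window centres, numeric `c(x, y)`.
#' @param object_radius_px access radius around each object window.
#' @param corridor_left,corridor_right corridor entry points, `c(x, y)`.
#' @param corridor_radius_px entry radius used to detect corridor visits.
#' @param nest_default default nest position used by the simulator.
#' @return An object of class `cage_layout`.
#' @export
cage_layout <- function(arena_w_px = 195, arena_h_px = 160, px_per_cm = 5,
                        object_left = c(10, 80), object_right = c(185, 80),
                        object_radius_px = 15,
                        corridor_left = c(25, 150), corridor_right = c(170, 150),
                        corridor_radius_px = 10,
                        nest_default = c(60, 30)) {
  stopifnot(px_per_cm > 0, object_radius_px > 0, corridor_radius_px > 0,
            arena_w_px > 0, arena_h_px > 0)
  if (sqrt(sum((object_left - object_right)^2)) <= 2 * object_radius_px)
    stop("left and right object windows must be disjoint")
  structure(list(
    arena_w_px = arena_w_px, arena_h_px = arena_h_px, px_per_cm = px_per_cm,
    object_left = object_left, object_right = object_right,
    object_radius_px = object_radius_px,
    corridor_left = corridor_left, corridor_right = corridor_right,
    corridor_radius_px = corridor_radius_px,
    nest_default = nest_default
  ), class = "cage_layout")
}

#' @export
print.cage_layout <- function(x, ...) {
  cat(sprintf("<cage_layout> %d x %d px at %.1f px/cm\n",
              x$arena_w_px, x$arena_h_px, x$px_per_cm))
  cat(sprintf("  objects L(%g,%g) R(%g,%g), radius %g px\n",
              x$object_left[1], x$object_left[2],
              x$object_right[1], x$object_right[2], x$object_radius_px))
  invisible(x)
}

object_center <- function(layout, side) {
  if (side == "left") layout$object_left else layout$object_right
}
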