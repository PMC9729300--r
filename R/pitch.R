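#' Pitch geometry
#'
#' The pitch is an axis-aligned rectangle in a Cartesian frame with the origin
#' at the pitch centre and the x-axis along the pitch length. Team A defends
#' the goal at `x = -length/2` and attacks towards `+x`; team B the reverse.
#' The 0.5 m patch grid is a rasterisation device only: agents move in
#' continuous coordinates, so `length` and `width` must be integer multiples
#' of `patch_size` but nothing else depends on the grid.
#'
#' @param length Pitch length in metres (goal line to goal line).
#' @param width Pitch width in metres.
#' @param patch_size Raster cell size in metres.
#' @param goal_width Width of the goal mouth in metres, centred on `y = 0`.
#'
#' @return An object of class `pitch_config`: a list with the four fields
#'   above plus the derived half-extents `xmax = length/2`, `ymax = width/2`.
#' @examples
#' p <- pitch_config()
#' p$length
#' @export
pitch_config <- function(length = 110, width = 60, patch_size = 0.5,
                         goal_width = 7.32) {
  if (length <= 0 || width <= 0 || patch_size <= 0) {
    abort("pitch dimensions and patch size must be positive",
          class = "kickmod_pitch_error")
  }
  is_mult <- function(a) abs(a / patch_size - round(a / patch_size)) < 1e-9
  if (!is_mult(length) || !is_mult(width)) {
    abort("length and width must be integer multiples of patch_size",
          class = "kickmod_pitch_error")
  }
  structure(
    list(length = length, width = width, patch_size = patch_size,
         goal_width = goal_width, xmax = length / 2, ymax = width / 2),
    class = "pitch_config"
  )
}

#' Clamp a point to the pitch rectangle
#'
#' Returns the nearest point of the (closed) pitch rectangle: the point itself
#' when already inside, otherwise the componentwise projection. Idempotent.
#'
#' @param p Numeric vector `c(x, y)` or a two-column matrix of points.
#' @param pitch A [pitch_config()].
#' @return A point (or matrix of points) inside the pitch.
#' @examples
#' clamp_to_pitch(c(60, 40), pitch_config())
#' @export
clamp_to_pitch <- function(p, pitch = pitch_config()) {
  if (is.matrix(p)) {
    p[, 1] <- pmin(pmax(p[, 1], -pitch$xmax), pitch$xmax)
    p[, 2] <- pmin(pmax(p[, 2], -pitch$ymax), pitch$ymax)
    return(p)
  }
  c(min(max(p[1], -pitch$xmax), pitch$xmax),
    min(max(p[2], -pitch$ymax), pitch$ymax))
}

#' Role boxes
#'
#' A role box is the axis-aligned rectangle a player's tactical role mostly
#' confines them to. Membership uses the closed-rectangle convention (points
#' on the boundary count as inside) so that agents do not oscillate at edges.
#'
#' @param role Role label, e.g. `"G"`, `"rCB"`, `"CMF"`, `"lF"`.
#' @param xmin,ymin,xmax,ymax Rectangle extents in pitch coordinates (metres).
#' @param owner Optional player id owning the box.
#' @return An object of class `role_box`.
#' @examples
#' b <- role_box("CF", -10, -10, 10, 10)
#' role_box_centre(b)
#' @export
role_box <- function(role, xmin, ymin, xmax, ymax, owner = NA_integer_) {
  if (xmin > xmax || ymin > ymax) {
    # normalise corner order so centroid/membership are order-invariant
    xs <- sort(c(xmin, xmax)); ys <- sort(c(ymin, ymax))
    xmin <- xs[1]; xmax <- xs[2]; ymin <- ys[1]; ymax <- ys[2]
  }
  structure(list(role = role, xmin = xmin, ymin = ymin,
                 xmax = xmax, ymax = ymax, owner = owner),
            class = "role_box")
}

#' @rdname role_box
#' @param box A [role_box()].
#' @param p Point `c(x, y)`.
#' @return `contains_point()`: logical.
#' @export
contains_point <- function(box, p) {
  p[1] >= box$xmin && p[1] <= box$xmax && p[2] >= box$ymin && p[2] <= box$ymax
}

#' @rdname role_box
#' @return `role_box_centre()`: the rectangle centroid `c(x, y)`.
#' @export
role_box_centre <- function(box) {
  c((box$xmin + box$xmax) / 2, (box$ymin + box$ymax) / 2)
}
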