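#' Pressure-plate geometry
#'
#' Describes the sensor grid of the dynamic weight bearing (DWB) cage: a
#' square Plexiglas arena whose floor is fully covered by a grid of vertical
#' force sensors sampled at a fixed frame rate. The default is the closest
#' square grid to the ~2000-sensor plate of the commercial device: 44 x 44 =
#' 1936 cells over a 25 x 25 cm arena, sampled at 30 Hz.
#'
#' Coordinate convention: the origin is the arena corner at cell (1, 1);
#' `x` runs rightward along columns and `y` forward along rows, both in cm.
#' A cell's centre is at `((col - 0.5) * cell_pitch, (row - 0.5) * cell_pitch)`.
#' Cell indices are 1-based.
#'
#' @param n_rows,n_cols Number of sensor rows/columns.
#' @param arena_side Side of the square arena in cm.
#' @param wall_margin Width in cm of the boundary band whose contacts count as
#'   "against the wall" (default: one cell pitch).
#' @param frame_rate Sampling frequency in Hz.
#' @return An object of class `plate_geometry`.
#' @examples
#' g <- plate_geometry()
#' g$n_rows * g$n_cols # 1936 sensors
#' @export
plate_geometry <- function(n_rows = 44L, n_cols = 44L, arena_side = 25,
                           wall_margin = NULL, frame_rate = 30) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  stopifnot(n_rows >= 4L, n_cols >= 4L, arena_side > 0, frame_rate > 0)
  cell_pitch <- arena_side / max(n_rows, n_cols)
  if (is.null(wall_margin)) wall_margin <- cell_pitch
  stopifnot(wall_margin >= 0, n_rows * cell_pitch <= arena_side + 1e-9)
  structure(
    list(
      n_rows = n_rows, n_cols = n_cols, cell_pitch = cell_pitch,
      arena_side = arena_side, wall_margin = wall_margin,
      frame_rate = frame_rate
    ),
    class = "plate_geometry"
  )
}

#' @export
print.plate_geometry <- function(x, ...) {
  cat(sprintf(
    "<plate_geometry> %d x %d cells (%.3f cm pitch), %g x %g cm arena, %g Hz\n",
    x$n_rows, x$n_cols, x$cell_pitch, x$arena_side, x$arena_side, x$frame_rate
  ))
  invisible(x)
}

# cell centre coordinates (cm) for 1-based row/col indices
cell_xy <- function(row, col, geometry) {
  list(
    x = (col - 0.5) * geometry$cell_pitch,
    y = (row - 0.5) * geometry$cell_pitch
  )
}

# TRUE when a cell centre lies within wall_margin of the arena boundary
cell_in_wall_band <- function(row, col, geometry) {
  p <- geometry$cell_pitch
  m <- geometry$wall_margin
  x <- (col - 0.5) * p
  y <- (row - 0.5) * p
  side_x <- geometry$n_cols * p
  side_y <- geometry$n_rows * p
  (x < m) | (side_x - x < m) | (y < m) | (side_y - y < m)
}
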