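#' @import data.table
NULL

# Connected-component labelling of activated cells under 8-connectivity.
# `cells` is a data.table(frame, row, col, load) already filtered to
# load >= threshold. Returns the table with a `blob` id (unique across the
# whole input). Components are found by iterated min-label propagation over
# the neighbour graph; blobs are tiny (a few cells) so this converges in a
# handful of sweeps.
label_active_cells <- function(cells, geometry) {
  n <- nrow(cells)
  if (n == 0L) {
    cells$blob <- integer(0)
    return(cells)
  }
  key <- (cells$frame - 1) * (geometry$n_rows * geometry$n_cols) +
    (cells$row - 1) * geometry$n_cols + cells$col
  idx <- data.table::data.table(cellkey = key, id = seq_len(n))
  data.table::setkey(idx, cellkey)
  offs <- expand.grid(dr = -1L:1L, dc = -1L:1L)
  offs <- offs[!(offs$dr == 0L & offs$dc == 0L), ]
  edges_a <- integer(0); edges_b <- integer(0)
  for (k in seq_len(nrow(offs))) {
    nb_key <- key + offs$dr[k] * geometry$n_cols + offs$dc[k]
    valid <- cells$row + offs$dr[k] >= 1L &
      cells$row + offs$dr[k] <= geometry$n_rows &
      cells$col + offs$dc[k] >= 1L &
      cells$col + offs$dc[k] <= geometry$n_cols
    m <- idx[data.table::data.table(cellkey = nb_key[valid]), id,
             on = "cellkey"]
    src <- which(valid)[!is.na(m)]
    dst <- m[!is.na(m)]
    edges_a <- c(edges_a, src)
    edges_b <- c(edges_b, dst)
  }
  lab <- seq_len(n)
  if (length(edges_a)) {
    repeat {
      new_lab <- lab
      # pull the smallest neighbour label across each edge (both directions)
      cand <- pmin(lab[edges_a], lab[edges_b])
      agg_a <- tapply(cand, edges_a, min)
      agg_b <- tapply(cand, edges_b, min)
      ia <- as.integer(names(agg_a)); ib <- as.integer(names(agg_b))
      new_lab[ia] <- pmin(new_lab[ia], agg_a)
      new_lab[ib] <- pmin(new_lab[ib], agg_b)
      # path compression: follow labels to their current root
      repeat {
        nl2 <- new_lab[new_lab]
        if (identical(nl2, new_lab)) break
        new_lab <- nl2
      }
      if (identical(new_lab, lab)) break
      lab <- new_lab
    }
  }
  cells$blob <- match(lab, sort(unique(lab)))
  cells
}

# principal-axis elongation of a cell set: sqrt of the ratio of the two
# eigenvalues of the load-weighted coordinate covariance
# (rotation-invariant, unlike a bounding-box aspect ratio, so diagonal lines
# register as elongated; load weighting keeps attached low-load speckle
# cells from masking an elongated shape)
blob_elongation <- function(row, col, load) {
  if (length(row) < 2L) return(1)
  v <- stats::cov.wt(cbind(row, col), wt = load / sum(load))$cov
  ev <- eigen(v, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= 1e-12) return(Inf)
  sqrt(ev[1] / ev[2])
}

# blob-level summary of labelled cells: load, weighted centroid, size,
# wall flag, bounding box and the (row, col) of the smallest member cell
summarise_blobs <- function(cells, geometry) {
  if (nrow(cells) == 0L) {
    return(data.table::data.table(
      frame = integer(0), blob = integer(0), load = numeric(0),
      x = numeric(0), y = numeric(0), n_cells = integer(0),
      touches_wall = logical(0), min_row = integer(0), min_col = integer(0),
      row_lo = integer(0), row_hi = integer(0),
      col_lo = integer(0), col_hi = integer(0), elongation = numeric(0)
    ))
  }
  p <- geometry$cell_pitch
  cells <- data.table::as.data.table(cells)
  cells[, `:=`(cx = (col - 0.5) * p, cy = (row - 0.5) * p,
               wall = cell_in_wall_band(row, col, geometry))]
  blobs <- cells[, list(
    load = sum(load),
    x = sum(load * cx) / sum(load),
    y = sum(load * cy) / sum(load),
    n_cells = .N,
    touches_wall = any(wall),
    min_row = min(row),
    min_col = col[which.min(row * (geometry$n_cols + 1L) + col)],
    row_lo = min(row), row_hi = max(row),
    col_lo = min(col), col_hi = max(col),
    elongation = blob_elongation(row, col, load)
  ), by = c("frame", "blob")]
  data.table::setorderv(blobs, c("frame", "load", "min_row", "min_col"),
                        order = c(1L, -1L, 1L, 1L))
  blobs
}

#' Detect contact blobs in one pressure frame
#'
#' Cells with load at or above `activation_threshold` are grouped into
#' connected components under 8-connectivity (diagonally adjacent paw-pad
#' cells merge). Components with fewer than `min_cells` cells are discarded.
#'
#' @param frame A `sensor_frame` (dense load matrix, see [session_frame()])
#'   or a plain numeric matrix of per-cell loads in g.
#' @param geometry The [plate_geometry()] the frame was recorded on.
#' @param activation_threshold Minimum per-cell load in g for a cell to count
#'   as activated (default 1 g).
#' @param min_cells Minimum component size in cells (default 1).
#' @return A data.frame of blobs sorted by decreasing load (ties broken by
#'   the row/col of the smallest member cell), with columns `frame`, `blob`,
#'   `load` (g), `x`, `y` (load-weighted centroid, cm), `n_cells`,
#'   `touches_wall`, and a list-column `cells` of member-cell (row, col)
#'   matrices.
#' @examples
#' g <- plate_geometry()
#' m <- matrix(0, g$n_rows, g$n_cols)
#' m[5:6, 5:6] <- 10
#' detect_blobs(m, g)
#' @export
detect_blobs <- function(frame, geometry, activation_threshold = 1,
                         min_cells = 1L) {
  stopifnot(activation_threshold > 0, min_cells >= 1L)
  m <- unclass(frame)
  if (!is.matrix(m)) stop("frame must be a matrix of per-cell loads")
  if (nrow(m) != geometry$n_rows || ncol(m) != geometry$n_cols) {
    stop("frame grid is ", nrow(m), " x ", ncol(m),
         " but geometry says ", geometry$n_rows, " x ", geometry$n_cols)
  }
  fi <- attr(frame, "index")
  if (is.null(fi)) fi <- 1L
  act <- which(m >= activation_threshold, arr.ind = TRUE)
  cells <- data.table::data.table(
    frame = rep(as.integer(fi), nrow(act)),
    row = as.integer(act[, 1]), col = as.integer(act[, 2]),
    load = m[act]
  )
  blobs <- detect_blobs_cells(cells, geometry, min_cells)
  blobs$tab
}

# shared core: labelled cells -> filtered blob table (+ cell membership)
detect_blobs_cells <- function(cells, geometry, min_cells) {
  lab <- label_active_cells(cells, geometry)
  blobs <- summarise_blobs(lab, geometry)
  if (min_cells > 1L) {
    keep <- blobs[blobs$n_cells >= min_cells,
                  c("frame", "blob"), with = FALSE]
    lab <- lab[keep, on = c("frame", "blob")]
    blobs <- blobs[blobs$n_cells >= min_cells, ]
  }
  member <- lab[, list(cells = list(cbind(row = row, col = col))),
                by = c("frame", "blob")]
  tab <- member[blobs, on = c("frame", "blob")]
  data.table::setorderv(tab, c("frame", "load", "min_row", "min_col"),
                        order = c(1L, -1L, 1L, 1L))
  data.table::setcolorder(tab, c("frame", "blob", "load", "x", "y",
                                 "n_cells", "touches_wall"))
  data.table::setattr(tab, "cell_pitch", geometry$cell_pitch)
  list(tab = tab, cells = lab)
}

#' Detect contact blobs across a whole session
#'
#' Session-level version of [detect_blobs()]: labels every frame of a
#' [simulate_session()] recording in one vectorised pass.
#'
#' @param recording A `session_recording`.
#' @inheritParams detect_blobs
#' @return A blob table as in [detect_blobs()], one group of rows per frame.
#'   Frames with no activated cells contribute no rows.
#' @export
detect_session <- function(recording, activation_threshold = 1,
                           min_cells = 1L) {
  stopifnot(inherits(recording, "session_recording"),
            activation_threshold > 0, min_cells >= 1L)
  cells <- recording$cells[recording$cells$load >= activation_threshold, ]
  detect_blobs_cells(cells, recording$geometry, min_cells)$tab
}

#' Flag blobs touching the arena wall
#'
#' Sets `touches_wall` to `TRUE` for every blob with at least one member cell
#' whose centre lies within `geometry$wall_margin` of the arena boundary.
#' Detection already computes this flag; this operation recomputes it from
#' the member cells, e.g. after changing the margin.
#'
#' @param blobs A blob table with a `cells` list-column (from
#'   [detect_blobs()] or [detect_session()]).
#' @param geometry A [plate_geometry()].
#' @return The blob table with `touches_wall` recomputed.
#' @export
flag_wall_contacts <- function(blobs, geometry) {
  blobs <- data.table::as.data.table(blobs)
  blobs$touches_wall <- vapply(blobs$cells, function(cm) {
    any(cell_in_wall_band(cm[, "row"], cm[, "col"], geometry))
  }, logical(1))
  blobs
}

#' Build the analyzable-time mask of a session
#'
#' A frame is excluded from analysis when any of its blobs touches the wall
#' or when the paw-assignment stage flagged it ambiguous (the deterministic
#' surrogate for the experimenter's manual exclusion of unreadable
#' sequences). Wall contact takes precedence as the recorded reason.
#'
#' @param blobs Session blob table (from [detect_session()]).
#' @param n_frames Total number of frames in the session.
#' @param ambiguous Logical vector of length `n_frames`: per-frame ambiguity
#'   flags from [assign_session()] (default: none).
#' @param frame_rate Frames per second, used to convert counts to seconds.
#' @param wall_min_load Minimum load in g for a wall-touching blob to exclude
#'   its frame; sensor speckle in the wall band is not a paw against the
#'   wall (default 5 g).
#' @return An object of class `analyzable_mask`: list with `analyzable`
#'   (logical per frame), `reason` (`"none"`, `"wall_contact"` or
#'   `"ambiguous_assignment"`), and `analyzed_time` in s.
#' @export
build_analyzable_mask <- function(blobs, n_frames, ambiguous = NULL,
                                  frame_rate = 30, wall_min_load = 5) {
  n_frames <- as.integer(n_frames)
  if (is.null(ambiguous)) ambiguous <- rep(FALSE, n_frames)
  if (length(ambiguous) != n_frames) {
    stop("ambiguous flags have length ", length(ambiguous),
         " but the session has ", n_frames, " frames")
  }
  wall <- rep(FALSE, n_frames)
  if (nrow(blobs)) {
    w <- unique(blobs$frame[blobs$touches_wall &
                              blobs$load >= wall_min_load])
    if (length(w) && (min(w) < 1L || max(w) > n_frames)) {
      stop("blob table refers to frames outside 1..", n_frames)
    }
    wall[w] <- TRUE
  }
  reason <- rep("none", n_frames)
  reason[ambiguous] <- "ambiguous_assignment"
  reason[wall] <- "wall_contact"
  analyzable <- reason == "none"
  structure(
    list(
      analyzable = analyzable, reason = reason,
      analyzed_time = sum(analyzable) / frame_rate,
      frame_rate = frame_rate
    ),
    class = "analyzable_mask"
  )
}

#' @export
print.analyzable_mask <- function(x, ...) {
  cat(sprintf(
    "<analyzable_mask> %d/%d frames analyzable (%.1f s); excluded: %d wall, %d ambiguous\n",
    sum(x$analyzable), length(x$analyzable), x$analyzed_time,
    sum(x$reason == "wall_contact"), sum(x$reason == "ambiguous_assignment")
  ))
  invisible(x)
}
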