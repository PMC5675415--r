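#' Paw assignment parameters
#'
#' Tuning constants for labelling blobs as anatomical supports and linking
#' them across frames. All values are conventions (the device's own
#' paw/sensor coincidence step is proprietary); defaults are chosen to track
#' the synthetic animal reliably.
#'
#' @param smoothing_window Frames over which body displacement is averaged to
#'   estimate the heading (default 15 frames = 0.5 s at 30 Hz).
#' @param min_displacement Minimum displacement (cm) over the window for the
#'   heading to be (re)defined; below it the last heading is carried over.
#'   The default (0.8 cm over 0.5 s, i.e. 1.6 cm/s) sits between the load
#'   centroid shifts caused by posture changes and true walking speed, so
#'   posture transitions do not masquerade as turns.
#' @param gate Maximum centroid displacement per frame (cm) for two
#'   observations of one identity to be linked.
#' @param max_gap Maximum gap (frames) bridged inside a contact interval;
#'   bridged loads are linearly interpolated.
#' @param min_paw_load Minimum blob load (g) for a blob to be a paw
#'   candidate; lighter blobs (sensor speckle) stay unlabelled.
#' @param max_paw_cells Maximum blob size (cells) for a paw candidate.
#' @param max_paw_load_fraction Paw candidates must carry less than this
#'   fraction of the frame's total load (must exceed 0.5: a rearing hind paw carries about half the frame load).
#' @param min_pose_load Blobs lighter than this (g) are ignored when
#'   computing the body centroid, so scattered sensor speckle cannot drag
#'   the pose.
#' @param belly_radius Blobs whose centroid lies within this distance (cm) of
#'   the body centroid are labelled BELLY.
#' @param belly_load_fraction A blob overlapping the body centroid and
#'   carrying at least this fraction of the frame load is BELLY regardless of
#'   size.
#' @param tail_aspect Minimum bounding-box aspect ratio for a trailing blob
#'   to be labelled TAIL.
#' @return A list of class `assign_params`.
#' @export
assign_params <- function(smoothing_window = 15L, min_displacement = 0.8,
                          gate = 2, max_gap = 2L, min_paw_load = 10,
                          max_paw_cells = 8L, max_paw_load_fraction = 0.6,
                          min_pose_load = 5, belly_radius = 1.8,
                          belly_load_fraction = 0.25, tail_aspect = 2.5) {
  structure(as.list(environment()), class = "assign_params")
}

PAW_IDS <- c("FL", "FR", "HL", "HR")
SUPPORT_IDS <- c(PAW_IDS, "TAIL", "BELLY")

#' Estimate the body pose of one frame
#'
#' The body centroid is the load-weighted mean of the frame's blob centroids.
#' The heading is the unit direction of the displacement between the mean
#' centroid of the last `smoothing_window` frames and the mean of the
#' `smoothing_window` frames before those (averaging over a full gait cycle
#' cancels the load-centroid wobble of walking); when the displacement is
#' below `min_displacement` the last defined heading is carried over (the
#' initial default is "facing up the plate", `(0, 1)`).
#'
#' @param blobs Blob table for one frame (needs columns `load`, `x`, `y`).
#' @param history Optional data.frame (or list) of prior poses (elements
#'   `x`, `y`, `heading_x`, `heading_y`), most recent last; only the last
#'   two smoothing windows are used.
#' @param params An [assign_params()].
#' @return A list `body_pose` with `x`, `y`, `heading` (length-2 unit vector)
#'   and `heading_defined`; `NULL` when the frame has no blobs (such frames
#'   are flagged ambiguous downstream).
#' @export
estimate_body_pose <- function(blobs, history = NULL,
                               params = assign_params()) {
  if (is.null(blobs) || nrow(blobs) == 0L) return(NULL)
  keep <- blobs$load >= params$min_pose_load
  if (!any(keep)) keep <- rep(TRUE, nrow(blobs))
  w <- blobs$load[keep]
  cx <- sum(w * blobs$x[keep]) / sum(w)
  cy <- sum(w * blobs$y[keep]) / sum(w)
  heading <- c(0, 1)
  defined <- FALSE
  nh <- if (is.null(history)) 0L else length(history$x)
  if (nh > 0L) {
    d <- smoothed_displacement(c(history$x, cx), c(history$y, cy),
                               params$smoothing_window)
    if (d$norm >= params$min_displacement) {
      heading <- c(d$dx, d$dy) / d$norm
      defined <- TRUE
    } else {
      heading <- c(history$heading_x[nh], history$heading_y[nh])
    }
  }
  structure(list(x = cx, y = cy, heading = heading,
                 heading_defined = defined), class = "body_pose")
}

# displacement between the mean position over the last `window` samples and
# the mean over the `window` samples before those
smoothed_displacement <- function(px, py, window) {
  i <- length(px)
  cur <- max(1L, i - window + 1L):i
  prev <- max(1L, i - 2L * window + 1L):max(1L, i - window)
  dx <- mean(px[cur]) - mean(px[prev])
  dy <- mean(py[cur]) - mean(py[prev])
  list(dx = dx, dy = dy, norm = sqrt(dx^2 + dy^2))
}

# body-frame coordinates: along = heading component, cross = leftward
body_frame_coords <- function(blobs, pose) {
  hx <- pose$heading[1]; hy <- pose$heading[2]
  dx <- blobs$x - pose$x
  dy <- blobs$y - pose$y
  list(along = dx * hx + dy * hy, cross = -dx * hy + dy * hx)
}

#' Label the blobs of one frame as anatomical supports
#'
#' A central blob near the load-weighted body centroid is BELLY; an
#' elongated blob trailing behind all paw candidates is TAIL. Remaining
#' compact blobs of plausible paw load are paw candidates. The body axis is
#' estimated from the candidate geometry itself (the principal axis of four
#' candidates; the perpendicular of the lateral pair for three or two), and
#' only its sign is taken from the prior orientation -- the displacement
#' heading of [estimate_body_pose()] at the start, then the previous frame's
#' axis. This makes the front/hind and left/right quadrant assignment immune
#' to the load-centroid wobble of walking. A lone lateral pair is read as the
#' hind paws (a rearing rat stands on its hind paws, never on its front paws
#' alone). A frame is flagged ambiguous when two blobs compete for one
#' identity or more than four paw candidates are present; ambiguity is a
#' flag, not an error, and such frames are later excluded from the
#' analyzable mask.
#'
#' @param blobs Blob table for one frame.
#' @param pose A `body_pose` from [estimate_body_pose()].
#' @param params An [assign_params()].
#' @param prior_heading Unit vector giving the previously known body
#'   orientation; defaults to `pose$heading`.
#' @return The blob table with an `identity` column (`NA` for unlabelled
#'   blobs); attributes `ambiguous` (flag) and `axis` (the oriented body
#'   axis used, `NULL` when no candidate geometry defined one).
#' @export
classify_blobs <- function(blobs, pose, params = assign_params(),
                           prior_heading = NULL) {
  stopifnot(!is.null(pose))
  if (is.null(prior_heading)) prior_heading <- pose$heading
  blobs <- data.table::as.data.table(blobs)
  n <- nrow(blobs)
  identity <- rep(NA_character_, n)
  ambiguous <- FALSE
  dx <- blobs$x - pose$x
  dy <- blobs$y - pose$y
  dist <- sqrt(dx^2 + dy^2)
  total <- sum(blobs$load)

  # belly: central blob near the load-weighted centroid (heading-free)
  belly <- dist <= params$belly_radius
  if (any(belly)) {
    b <- which(belly)[which.min(dist[belly])]
    identity[b] <- "BELLY"
  }

  aspect <- if ("elongation" %in% names(blobs)) blobs$elongation else
    rep(1, n)
  # paw candidates: compact (never elongated), plausibly loaded, not belly
  cand <- is.na(identity) &
    blobs$load >= params$min_paw_load &
    blobs$load < params$max_paw_load_fraction * total &
    blobs$n_cells <= params$max_paw_cells &
    aspect < params$tail_aspect
  ci <- which(cand)
  k <- length(ci)

  # oriented body axis from candidate geometry, sign from the prior
  orient <- function(a) {
    a <- a / sqrt(sum(a^2))
    if (sum(a * prior_heading) < 0) -a else a
  }
  axis <- NULL
  if (k == 4L) {
    pts <- cbind(blobs$x[ci], blobs$y[ci])
    pc <- eigen(stats::cov(pts), symmetric = TRUE)$vectors[, 1]
    axis <- orient(pc)
  } else if (k %in% c(2L, 3L)) {
    pts <- cbind(blobs$x[ci], blobs$y[ci])
    dmat <- as.matrix(stats::dist(pts))
    diag(dmat) <- Inf
    pr <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
    sep <- pts[pr[2], ] - pts[pr[1], ]
    sep_unit <- sep / sqrt(sum(sep^2))
    prior_cross <- abs(sep_unit[1] * prior_heading[2] -
                         sep_unit[2] * prior_heading[1])
    if (k == 3L || prior_cross > abs(sum(sep_unit * prior_heading))) {
      # the closest pair is a lateral (left/right) pair: the body axis is
      # its perpendicular
      axis <- orient(c(-sep[2], sep[1]))
    } else {
      axis <- prior_heading # diagonal two-point support: keep the prior
    }
  } else {
    axis <- prior_heading
  }
  lx <- -axis[2]; ly <- axis[1] # leftward unit vector
  along <- dx * axis[1] + dy * axis[2]
  cross <- dx * lx + dy * ly

  if (k > 4L) {
    ambiguous <- TRUE
  } else if (k > 0L) {
    al <- along[ci]; cr <- cross[ci]
    lab <- rep(NA_character_, k)
    side <- function(v) ifelse(v > 0, "L", "R")
    if (k == 4L) {
      ord <- order(al, decreasing = TRUE)
      lab[ord[1:2]] <- paste0("F", side(cr[ord[1:2]]))
      lab[ord[3:4]] <- paste0("H", side(cr[ord[3:4]]))
    } else if (k == 3L) {
      pts <- cbind(blobs$x[ci], blobs$y[ci])
      dmat <- as.matrix(stats::dist(pts))
      diag(dmat) <- Inf
      pr <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
      pair <- sort(pr)
      single <- setdiff(1:3, pair)
      girdle <- if (al[single] > mean(al[pair])) c("F", "H") else c("H", "F")
      lab[single] <- paste0(girdle[1], side(cr[single]))
      lab[pair] <- paste0(girdle[2], side(cr[pair]))
    } else if (k == 2L) {
      if (abs(cr[1] - cr[2]) >= abs(al[1] - al[2])) {
        lab <- paste0("H", side(cr)) # lone lateral pair: rearing
      } else {
        fr <- which.max(al)
        lab[fr] <- paste0("F", side(cr[fr]))
        lab[-fr] <- paste0("H", side(cr[-fr]))
      }
    } else {
      lab <- paste0(if (al > 0) "F" else "H", side(cr))
    }
    if (anyDuplicated(lab[!is.na(lab)])) {
      ambiguous <- TRUE
    } else {
      identity[ci] <- lab
    }
  }

  # tail: elongated blob trailing behind every paw candidate
  behind_all <- if (k > 0L) along < min(along[ci]) else along < 0
  tail_blob <- is.na(identity) & !cand & aspect >= params$tail_aspect &
    behind_all
  if (any(tail_blob)) {
    tb <- which(tail_blob)[which.min(along[tail_blob])]
    identity[tb] <- "TAIL"
  }

  blobs$identity <- identity
  data.table::setattr(blobs, "ambiguous", ambiguous)
  data.table::setattr(blobs, "axis",
                      if (k >= 2L && !ambiguous) axis else NULL)
  blobs
}

#' Assign supports across a whole session
#'
#' Runs [estimate_body_pose()] and [classify_blobs()] frame by frame, then
#' links the labels into [link_tracks()] contact tracks.
#'
#' @param blobs Session blob table from [detect_session()].
#' @param n_frames Number of frames in the session.
#' @param params An [assign_params()].
#' @return A list of class `assignment` with `labels` (blob table plus
#'   `identity`), `ambiguous` (logical per frame; empty frames are flagged),
#'   `poses` (per-frame body pose table) and `tracks` (see [link_tracks()]).
#' @export
assign_session <- function(blobs, n_frames, params = assign_params()) {
  n_frames <- as.integer(n_frames)
  pitch <- attr(blobs, "cell_pitch")
  blobs <- data.table::as.data.table(blobs)
  frames_list <- split(blobs, by = "frame", keep.by = TRUE)
  if (!is.null(pitch)) {
    for (fb in frames_list) data.table::setattr(fb, "cell_pitch", pitch)
  }
  ambiguous <- rep(FALSE, n_frames)
  poses <- data.table::data.table(
    frame = seq_len(n_frames), x = NA_real_, y = NA_real_,
    heading_x = NA_real_, heading_y = NA_real_
  )
  # preallocated pose history; only the last 2 smoothing windows are handed
  # to the pose estimator
  hist_x <- numeric(n_frames); hist_y <- numeric(n_frames)
  hist_hx <- numeric(n_frames); hist_hy <- numeric(n_frames)
  n_hist <- 0L
  win2 <- 2L * params$smoothing_window
  labelled <- vector("list", n_frames)
  cur_heading <- NULL # last oriented body axis from the classifier
  for (i in seq_len(n_frames)) {
    fb <- frames_list[[as.character(i)]]
    if (is.null(fb) || nrow(fb) == 0L) {
      ambiguous[i] <- TRUE
      # carry the last pose so the history window stays aligned
      if (n_hist > 0L) {
        n_hist <- n_hist + 1L
        hist_x[n_hist] <- hist_x[n_hist - 1L]
        hist_y[n_hist] <- hist_y[n_hist - 1L]
        hist_hx[n_hist] <- hist_hx[n_hist - 1L]
        hist_hy[n_hist] <- hist_hy[n_hist - 1L]
      }
      next
    }
    history <- if (n_hist > 0L) {
      sl <- max(1L, n_hist - win2 + 1L):n_hist
      list(x = hist_x[sl], y = hist_y[sl],
           heading_x = hist_hx[sl], heading_y = hist_hy[sl])
    } else NULL
    pose <- estimate_body_pose(fb, history = history, params = params)
    lab <- classify_blobs(fb, pose, params, prior_heading = cur_heading)
    ambiguous[i] <- isTRUE(attr(lab, "ambiguous"))
    if (!is.null(attr(lab, "axis"))) cur_heading <- attr(lab, "axis")
    labelled[[i]] <- lab
    n_hist <- n_hist + 1L
    hist_x[n_hist] <- pose$x; hist_y[n_hist] <- pose$y
    hist_hx[n_hist] <- pose$heading[1]
    hist_hy[n_hist] <- pose$heading[2]
    poses$x[i] <- pose$x; poses$y[i] <- pose$y
    poses$heading_x[i] <- pose$heading[1]
    poses$heading_y[i] <- pose$heading[2]
  }
  labels <- data.table::rbindlist(labelled[!vapply(labelled, is.null,
                                                   logical(1))])
  tracks <- link_tracks(labels, n_frames, params)
  structure(list(labels = labels, ambiguous = ambiguous, poses = poses,
                 tracks = tracks),
            class = "assignment")
}

#' Link per-frame labels into contact tracks
#'
#' For each identity, consecutive observations are associated when the
#' centroid moves at most `gate` cm per frame. Gaps of at most `max_gap`
#' frames inside a contact are bridged with linearly interpolated load;
#' longer gaps (or gate violations) split the contact into separate
#' intervals.
#'
#' @param labels Labelled blob table (columns `frame`, `identity`, `load`,
#'   `x`, `y`).
#' @param n_frames Number of frames in the session.
#' @param params An [assign_params()].
#' @return A list of class `paw_tracks`: `load` (an `n_frames` x 6 matrix in
#'   g, columns FL, FR, HL, HR, TAIL, BELLY; 0 when not in contact),
#'   `intervals` (data.frame identity/start/end with half-open
#'   `[start, end)` frame intervals) and `n_frames`.
#' @export
link_tracks <- function(labels, n_frames, params = assign_params()) {
  n_frames <- as.integer(n_frames)
  load <- matrix(0, n_frames, length(SUPPORT_IDS),
                 dimnames = list(NULL, SUPPORT_IDS))
  ivals <- list()
  labels <- data.table::as.data.table(labels)
  for (id in SUPPORT_IDS) {
    obs <- labels[!is.na(labels$identity) & labels$identity == id, ]
    if (nrow(obs) == 0L) next
    data.table::setorderv(obs, "frame")
    f <- obs$frame
    gap <- diff(f)
    jump <- sqrt(diff(obs$x)^2 + diff(obs$y)^2)
    linked <- gap <= params$max_gap + 1L & jump <= params$gate * gap
    seg <- cumsum(c(1L, as.integer(!linked)))
    for (s in unique(seg)) {
      si <- which(seg == s)
      fr <- f[si]
      ld <- obs$load[si]
      # fill observed frames, interpolate across bridged gaps
      full <- fr[1]:fr[length(fr)]
      load[full, id] <- if (length(fr) == 1L) ld else
        stats::approx(fr, ld, xout = full)$y
      ivals[[length(ivals) + 1L]] <- data.frame(
        identity = id, start = fr[1], end = fr[length(fr)] + 1L
      )
    }
  }
  intervals <- if (length(ivals)) do.call(rbind, ivals) else
    data.frame(identity = character(0), start = integer(0), end = integer(0))
  structure(list(load = load, intervals = intervals, n_frames = n_frames),
            class = "paw_tracks")
}

#' @export
print.paw_tracks <- function(x, ...) {
  cat(sprintf("<paw_tracks> %d frames, %d contact intervals\n",
              x$n_frames, nrow(x$intervals)))
  invisible(x)
}
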