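#' Simulation configuration
#'
#' Physical and numerical settings for one synthetic session on the pressure
#' plate. Defaults state a 5-minute recording of a 300 g adult rat (the usual
#' 250-350 g range), a small tail/belly load fraction consistent with axis
#' weight percentages that sum to slightly under 100% of body weight, and a
#' mild per-cell sensor noise.
#'
#' @param duration Session length in s (default 300 s = 5 min).
#' @param body_weight Animal weight in g.
#' @param noise_sd Per-cell zero-mean Gaussian noise standard deviation in g;
#'   cell values are truncated at 0. Set to 0 for noise-free frames.
#' @param noise_floor Sensor quantisation floor in g: noisy cell values below
#'   this are recorded as 0 (keeps recordings sparse, as real devices do not
#'   report sub-gram readings on idle cells). Ignored when `noise_sd = 0`.
#' @param tail_belly_load_fraction Fraction of body weight resting on the tail
#'   and belly in quadruped stance (default 0.02, i.e. paws carry ~98% of
#'   body weight).
#' @param animal_id Identifier stored in the session metadata.
#' @param seed Integer RNG seed; identical seeds give bit-identical sessions.
#' @param geometry A [plate_geometry()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(duration = 300, body_weight = 300, noise_sd = 0.5,
                       noise_floor = 0.5, tail_belly_load_fraction = 0.02,
                       animal_id = "rat01", seed = 1L,
                       geometry = plate_geometry()) {
  stopifnot(
    duration > 0, body_weight > 0, noise_sd >= 0, noise_floor >= 0,
    tail_belly_load_fraction >= 0, tail_belly_load_fraction <= 0.3,
    inherits(geometry, "plate_geometry")
  )
  structure(
    list(
      duration = duration, body_weight = body_weight, noise_sd = noise_sd,
      noise_floor = noise_floor,
      tail_belly_load_fraction = tail_belly_load_fraction,
      animal_id = animal_id, seed = as.integer(seed), geometry = geometry
    ),
    class = "sim_config"
  )
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# behavioural states
STATE_LEVELS <- c("quadruped", "rearing", "locomotion", "wall_lean")

# mean dwell times per state, in seconds
STATE_MEAN_DWELL <- c(quadruped = 2.0, rearing = 1.5, locomotion = 1.5,
                      wall_lean = 1.5)

# paw-borne front fraction of a healthy quadruped (hind paws carry ~3/4)
BASE_FRONT_FRACTION <- 0.26

# body-frame support offsets in cm: along (heading) and cross (leftward)
SUPPORT_OFFSETS <- list(
  FL = c(along = 3.5, cross = 1.8),
  FR = c(along = 3.5, cross = -1.8),
  HL = c(along = -2.5, cross = 2.2),
  HR = c(along = -2.5, cross = -2.2)
)
# when rearing, the hind paws step forward under the body, which keeps the
# load-weighted support centroid continuous across posture transitions
REAR_HIND_ALONG <- -1.2
# fraction of body weight resting on the tail/haunches while rearing: a
# rearing rat sits back, so each hind paw bears about the same load as in
# quadruped stance (keeps per-paw contact means posture-independent, as the
# published healthy hind/front percentages require)
REAR_TAIL_FRACTION <- 0.25
BODY_SAFE_MARGIN <- 8.6   # cm between body centre and walls (tail included)
LOCO_SPEED <- 3.0         # cm/s during locomotion
GAIT_PERIOD <- 0.5        # s per stride cycle
GAIT_PHASE <- c(FL = 0.0, HR = 0.25, FR = 0.5, HL = 0.75)
GAIT_DUTY <- 0.75         # fraction of cycle a paw is in contact
# body-weight fraction transferred to the wall while leaning; kept small so
# the load-centroid shift at bout boundaries stays below the tracker's
# heading displacement threshold
WALL_LEAN_FRACTION <- 0.05

# Draw a state-per-frame schedule. Segments have exponential dwell times;
# each segment's state is sampled with probabilities tilted by the remaining
# occupancy deficit, which pins empirical occupancy to the configured rates
# to within a couple of dwell lengths over the session.
schedule_states <- function(phenotype, n_frames, frame_rate) {
  target <- c(
    quadruped = 1 - phenotype$rearing_rate - phenotype$wall_lean_rate -
      phenotype$locomotion_rate,
    rearing = phenotype$rearing_rate,
    locomotion = phenotype$locomotion_rate,
    wall_lean = phenotype$wall_lean_rate
  )
  m <- STATE_MEAN_DWELL * frame_rate # mean dwell in frames
  spent <- c(quadruped = 0, rearing = 0, locomotion = 0, wall_lean = 0)
  states <- integer(n_frames)
  bout <- integer(n_frames)
  filled <- 0L
  b <- 0L
  while (filled < n_frames) {
    deficit <- pmax(target * n_frames - spent, 0)
    w <- deficit / m
    if (sum(w) <= 0) w <- target / m
    st <- sample.int(4L, 1L, prob = w)
    d <- max(1L, as.integer(round(stats::rexp(1L, rate = 1 / m[st]))))
    d <- min(d, n_frames - filled)
    b <- b + 1L
    states[(filled + 1L):(filled + d)] <- st
    bout[(filled + 1L):(filled + d)] <- b
    spent[st] <- spent[st] + d
    filled <- filled + d
  }
  list(state = states, bout = bout)
}

# Body trajectory: stationary in static states, constant-speed translation
# with wall reflection during locomotion. Returns per-frame position and the
# smoothed (rendered) heading computed exactly like the tracker does, so the
# simulated animal turns gradually rather than pivoting instantaneously.
body_trajectory <- function(schedule, geometry, frame_rate) {
  n <- length(schedule$state)
  side <- geometry$arena_side
  lo <- BODY_SAFE_MARGIN
  hi <- side - BODY_SAFE_MARGIN
  px <- numeric(n); py <- numeric(n)
  x <- side / 2; y <- side / 2
  hx <- 0; hy <- 1 # instantaneous movement direction
  step <- LOCO_SPEED / frame_rate
  prev_bout <- 0L
  for (i in seq_len(n)) {
    if (schedule$state[i] == 3L) { # locomotion
      if (schedule$bout[i] != prev_bout) {
        ang <- stats::runif(1L, 0, 2 * pi)
        hx <- cos(ang); hy <- sin(ang)
      }
      x <- x + step * hx
      y <- y + step * hy
      if (x < lo) { x <- 2 * lo - x; hx <- -hx }
      if (x > hi) { x <- 2 * hi - x; hx <- -hx }
      if (y < lo) { y <- 2 * lo - y; hy <- -hy }
      if (y > hi) { y <- 2 * hi - y; hy <- -hy }
    }
    prev_bout <- schedule$bout[i]
    px[i] <- x; py[i] <- y
  }
  # rendered heading: the body turns toward its direction of travel at a
  # bounded rate (rats do not pivot instantaneously), so the paw layout
  # rotates smoothly even across wall reflections and new walking bouts
  max_turn <- 12 * pi / 180 # rad per frame
  hdx <- numeric(n); hdy <- numeric(n)
  theta <- pi / 2 # facing +y
  for (i in seq_len(n)) {
    if (schedule$state[i] == 3L) {
      j <- min(i + 1L, n) # movement direction over this step
      mdx <- if (i < n) px[j] - px[i] else px[i] - px[i - 1L]
      mdy <- if (i < n) py[j] - py[i] else py[i] - py[i - 1L]
      if (mdx != 0 || mdy != 0) {
        target <- atan2(mdy, mdx)
        delta <- (target - theta + pi) %% (2 * pi) - pi
        theta <- theta + max(-max_turn, min(max_turn, delta))
      }
    }
    hdx[i] <- cos(theta); hdy[i] <- sin(theta)
  }
  list(x = px, y = py, hx = hdx, hy = hdy)
}

# Per-frame true support loads in g, columns FL FR HL HR TAIL BELLY WALL.
support_loads <- function(schedule, phenotype, config) {
  n <- length(schedule$state)
  W <- config$body_weight
  tb <- config$tail_belly_load_fraction
  f <- min(max(BASE_FRONT_FRACTION + phenotype$ap_bias, 0.01), 0.99)
  r <- min(max(0.5 + phenotype$lateral_bias, 0.01), 0.99)
  share <- c(FL = f * (1 - r), FR = f * r, HL = (1 - f) * (1 - r),
             HR = (1 - f) * r)
  loads <- matrix(0, nrow = n, ncol = 7,
                  dimnames = list(NULL, c("FL", "FR", "HL", "HR",
                                          "TAIL", "BELLY", "WALL")))
  st <- schedule$state
  # quadruped: four paws + belly/tail
  q <- st == 1L
  if (any(q)) {
    paw_total <- W * (1 - tb)
    loads[q, c("FL", "FR", "HL", "HR")] <-
      matrix(share * paw_total, sum(q), 4, byrow = TRUE)
    loads[q, "TAIL"] <- tb * W / 2
    loads[q, "BELLY"] <- tb * W / 2
  }
  # rearing: hind paws only, sitting back on the tail/haunches
  re <- st == 2L
  if (any(re)) {
    paw_total <- W * (1 - REAR_TAIL_FRACTION)
    loads[re, "HL"] <- paw_total * (1 - r)
    loads[re, "HR"] <- paw_total * r
    loads[re, "TAIL"] <- REAR_TAIL_FRACTION * W
  }
  # locomotion: one paw in swing at any time, shares renormalised
  lo <- st == 3L
  if (any(lo)) {
    idx <- which(lo)
    period <- max(1L, as.integer(round(GAIT_PERIOD * config$geometry$frame_rate)))
    # frame index within each locomotion bout
    k <- stats::ave(seq_along(idx), schedule$bout[idx],
                    FUN = function(v) seq_along(v) - 1L)
    paw_total <- W * (1 - tb)
    contact <- sapply(names(GAIT_PHASE), function(p) {
      ((k / period + GAIT_PHASE[[p]]) %% 1) < GAIT_DUTY
    })
    contact <- matrix(contact, nrow = length(idx),
                      dimnames = list(NULL, names(GAIT_PHASE)))
    contact <- contact[, c("FL", "FR", "HL", "HR"), drop = FALSE]
    sh <- matrix(share, length(idx), 4, byrow = TRUE) * contact
    sh <- sh / rowSums(sh)
    loads[idx, c("FL", "FR", "HL", "HR")] <- sh * paw_total
    loads[idx, "TAIL"] <- tb * W
  }
  # wall lean: quadruped layout with part of the weight on the wall
  wl <- st == 4L
  if (any(wl)) {
    paw_total <- W * (1 - tb - WALL_LEAN_FRACTION)
    loads[wl, c("FL", "FR", "HL", "HR")] <-
      matrix(share * pmax(paw_total, 0), sum(wl), 4, byrow = TRUE)
    loads[wl, "TAIL"] <- tb * W / 2
    loads[wl, "BELLY"] <- tb * W / 2
    loads[wl, "WALL"] <- WALL_LEAN_FRACTION * W
  }
  loads
}

# 2x2 block anchor (top-left row/col) whose centre is nearest (x, y)
block2_anchor <- function(x, y, geometry) {
  p <- geometry$cell_pitch
  r0 <- pmin(pmax(round(y / p), 1L), geometry$n_rows - 1L)
  c0 <- pmin(pmax(round(x / p), 1L), geometry$n_cols - 1L)
  list(r0 = as.integer(r0), c0 = as.integer(c0))
}

#' Simulate one session on the pressure plate
#'
#' Generates a synthetic recording of a rat moving freely on the sensor grid,
#' together with per-frame ground truth. The animal alternates quadruped
#' stance, bipedal rearing, locomotion and wall leaning following a
#' segment-wise stochastic schedule whose empirical occupancies are pinned to
#' the configured rates. Each loaded support is rendered as a compact cell
#' cluster: paws as 2x2 blocks, the belly as a 3x3 block, the tail as a short
#' line of cells trailing the body; during wall leaning an extra blob is
#' placed in the wall band. Per-cell Gaussian noise (truncated at zero,
#' quantised at `noise_floor`) is added when `noise_sd > 0`.
#'
#' @param phenotype A [phenotype_params()] object.
#' @param config A [sim_config()] object.
#' @return A list of class `dwb_session` with elements `recording` (class
#'   `session_recording`: metadata, geometry and a sparse cell table with
#'   columns frame, row, col, load) and `truth` (class `session_truth`: a
#'   data.frame with per-frame state, true support loads in g -- including
#'   tail, belly and wall -- true paw centroids in cm, and the body position
#'   and rendered heading).
#' @examples
#' s <- simulate_session(make_phenotype_profile("D0"),
#'                       sim_config(duration = 5, noise_sd = 0, seed = 1))
#' table(s$truth$state)
#' @export
simulate_session <- function(phenotype, config = sim_config()) {
  stopifnot(inherits(phenotype, "phenotype_params"),
            inherits(config, "sim_config"))
  geometry <- config$geometry
  n_frames <- as.integer(floor(config$duration * geometry$frame_rate))
  if (n_frames < 2L) {
    stop("duration ", config$duration, " s yields ", n_frames,
         " frame(s); at least 2 are required")
  }
  with_seed(config$seed, {
    schedule <- schedule_states(phenotype, n_frames, geometry$frame_rate)
    traj <- body_trajectory(schedule, geometry, geometry$frame_rate)
    loads <- support_loads(schedule, phenotype, config)

    # left vector = heading rotated +90 degrees
    lx <- -traj$hy; ly <- traj$hx
    paws <- c("FL", "FR", "HL", "HR")
    cells_parts <- list()
    truth_cent <- matrix(NA_real_, n_frames, 8,
                         dimnames = list(NULL, as.vector(
                           t(outer(c("x_", "y_"), paws, paste0)))))
    rearing <- schedule$state == 2L
    for (pw in paws) {
      off <- SUPPORT_OFFSETS[[pw]]
      along <- rep(off[["along"]], n_frames)
      if (pw %in% c("HL", "HR")) along[rearing] <- REAR_HIND_ALONG
      x <- traj$x + along * traj$hx + off[["cross"]] * lx
      y <- traj$y + along * traj$hy + off[["cross"]] * ly
      a <- block2_anchor(x, y, geometry)
      loaded <- which(loads[, pw] > 0)
      p <- geometry$cell_pitch
      truth_cent[loaded, paste0("x_", pw)] <- a$c0[loaded] * p
      truth_cent[loaded, paste0("y_", pw)] <- a$r0[loaded] * p
      if (length(loaded)) {
        cells_parts[[pw]] <- data.table::data.table(
          frame = rep(loaded, each = 4L),
          row = as.vector(rbind(a$r0[loaded], a$r0[loaded],
                                a$r0[loaded] + 1L, a$r0[loaded] + 1L)),
          col = as.vector(rbind(a$c0[loaded], a$c0[loaded] + 1L,
                                a$c0[loaded], a$c0[loaded] + 1L)),
          load = rep(loads[loaded, pw] / 4, each = 4L)
        )
      }
    }
    # belly: 3x3 block centred on the body cell
    bl <- which(loads[, "BELLY"] > 0)
    if (length(bl)) {
      p <- geometry$cell_pitch
      rc <- pmin(pmax(as.integer(round(traj$y[bl] / p + 0.5)), 2L),
                 geometry$n_rows - 1L)
      cc <- pmin(pmax(as.integer(round(traj$x[bl] / p + 0.5)), 2L),
                 geometry$n_cols - 1L)
      dr <- rep(-1L:1L, times = 3L)
      dc <- rep(-1L:1L, each = 3L)
      cells_parts[["BELLY"]] <- data.table::data.table(
        frame = rep(bl, each = 9L),
        row = as.vector(outer(dr, rc, `+`)),
        col = as.vector(outer(dc, cc, `+`)),
        load = rep(loads[bl, "BELLY"] / 9, each = 9L)
      )
    }
    # tail: six single cells trailing the body along -heading
    tl <- which(loads[, "TAIL"] > 0)
    if (length(tl)) {
      p <- geometry$cell_pitch
      dist <- 4.8 + p * (0:5)
      tail_dt <- data.table::rbindlist(lapply(seq_along(dist), function(k) {
        x <- traj$x[tl] - dist[k] * traj$hx[tl]
        y <- traj$y[tl] - dist[k] * traj$hy[tl]
        data.table::data.table(
          frame = tl,
          row = pmin(pmax(as.integer(ceiling(y / p)), 1L), geometry$n_rows),
          col = pmin(pmax(as.integer(ceiling(x / p)), 1L), geometry$n_cols),
          load = loads[tl, "TAIL"] / length(dist)
        )
      }))
      cells_parts[["TAIL"]] <- tail_dt
    }
    # wall blob: single cell of the outermost ring nearest the body
    wl <- which(loads[, "WALL"] > 0)
    if (length(wl)) {
      x <- traj$x[wl]; y <- traj$y[wl]
      side_x <- geometry$n_cols * geometry$cell_pitch
      side_y <- geometry$n_rows * geometry$cell_pitch
      dists <- cbind(x, side_x - x, y, side_y - y)
      nearest <- max.col(-dists, ties.method = "first")
      p <- geometry$cell_pitch
      row <- as.integer(pmin(pmax(ceiling(y / p), 1L), geometry$n_rows))
      col <- as.integer(pmin(pmax(ceiling(x / p), 1L), geometry$n_cols))
      row[nearest == 3L] <- 1L
      row[nearest == 4L] <- geometry$n_rows
      col[nearest == 1L] <- 1L
      col[nearest == 2L] <- geometry$n_cols
      cells_parts[["WALL"]] <- data.table::data.table(
        frame = wl, row = row, col = col, load = loads[wl, "WALL"]
      )
    }
    cells <- data.table::rbindlist(cells_parts)
    # cells rendered onto the same grid position accumulate
    cells <- cells[, list(load = sum(load)), by = c("frame", "row", "col")]

    if (config$noise_sd > 0) {
      cells <- add_sensor_noise(cells, n_frames, geometry,
                                config$noise_sd, config$noise_floor)
    }
    data.table::setkeyv(cells, c("frame", "row", "col"))

    recording <- structure(
      list(
        meta = list(
          animal_id = config$animal_id, body_weight = config$body_weight,
          day = phenotype$day, condition = phenotype$condition,
          seed = config$seed, duration = config$duration,
          n_frames = n_frames, noise_sd = config$noise_sd,
          noise_floor = config$noise_floor,
          tail_belly_load_fraction = config$tail_belly_load_fraction
        ),
        geometry = geometry,
        n_frames = n_frames,
        cells = cells
      ),
      class = "session_recording"
    )
    truth <- data.table::data.table(
      frame = seq_len(n_frames),
      state = STATE_LEVELS[schedule$state],
      load_FL = loads[, "FL"], load_FR = loads[, "FR"],
      load_HL = loads[, "HL"], load_HR = loads[, "HR"],
      load_TAIL = loads[, "TAIL"], load_BELLY = loads[, "BELLY"],
      load_WALL = loads[, "WALL"]
    )
    truth <- cbind(truth, data.table::as.data.table(truth_cent))
    truth$body_x <- traj$x
    truth$body_y <- traj$y
    truth$head_x <- traj$hx
    truth$head_y <- traj$hy
    data.table::setattr(truth, "class",
                        c("session_truth", class(truth)))
    structure(list(recording = recording, truth = truth),
              class = "dwb_session")
  })
}

# truncated-Gaussian sensor noise with a quantisation floor, drawn in fixed
# frame order (chunked to bound memory) so sessions are seed-reproducible
add_sensor_noise <- function(cells, n_frames, geometry, sd, floor_g) {
  n_cells <- geometry$n_rows * geometry$n_cols
  chunk <- max(1L, as.integer(2e6 %/% n_cells))
  out <- vector("list", ceiling(n_frames / chunk))
  ci <- 0L
  for (start in seq(1L, n_frames, by = chunk)) {
    end <- min(start + chunk - 1L, n_frames)
    nf <- end - start + 1L
    eps <- stats::rnorm(nf * n_cells, 0, sd)
    sub <- cells[cells$frame >= start & cells$frame <= end, ]
    flat <- (sub$frame - start) * n_cells +
      (sub$row - 1L) * geometry$n_cols + sub$col
    dense <- numeric(nf * n_cells)
    dense[flat] <- sub$load
    dense <- pmax(dense + eps, 0)
    keep <- which(dense >= floor_g)
    ci <- ci + 1L
    out[[ci]] <- data.table::data.table(
      frame = start + (keep - 1L) %/% n_cells,
      row = as.integer(((keep - 1L) %% n_cells) %/% geometry$n_cols + 1L),
      col = as.integer((keep - 1L) %% geometry$n_cols + 1L),
      load = dense[keep]
    )
  }
  data.table::rbindlist(out)
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf(
    "<session_recording> %s %s/%s: %d frames (%.0f s at %g Hz), %d nonzero cells\n",
    x$meta$animal_id, x$meta$day, x$meta$condition, x$n_frames,
    x$meta$duration, x$geometry$frame_rate, nrow(x$cells)
  ))
  invisible(x)
}

#' Extract one dense frame from a recording
#'
#' @param recording A `session_recording`.
#' @param index Frame number (1-based).
#' @return A `sensor_frame`: the dense load matrix (g) with attributes
#'   `index` and `time` (s).
#' @export
session_frame <- function(recording, index) {
  stopifnot(inherits(recording, "session_recording"),
            index >= 1L, index <= recording$n_frames)
  g <- recording$geometry
  m <- matrix(0, g$n_rows, g$n_cols)
  sub <- recording$cells[recording$cells$frame == index, ]
  if (nrow(sub)) m[cbind(sub$row, sub$col)] <- sub$load
  structure(m, index = as.integer(index),
            time = (index - 1) / g$frame_rate, class = "sensor_frame")
}
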