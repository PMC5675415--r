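# shared fixtures and independent oracles for the test suite

quick_session <- function(day = "D0", seed = 1L, duration = 20,
                          noise_sd = 0, ...) {
  simulate_session(
    make_phenotype_profile(day),
    sim_config(duration = duration, noise_sd = noise_sd, seed = seed, ...)
  )
}

# build a paw_tracks object directly from a load matrix (columns named)
make_tracks <- function(load) {
  full <- matrix(0, nrow(load), 6,
                 dimnames = list(NULL, c("FL", "FR", "HL", "HR",
                                         "TAIL", "BELLY")))
  full[, colnames(load)] <- load
  structure(list(load = full, intervals = NULL, n_frames = nrow(load)),
            class = "paw_tracks")
}

# mask with all frames analyzable
full_mask <- function(n, frame_rate = 30) {
  build_analyzable_mask(
    data.frame(frame = integer(0), touches_wall = logical(0),
               load = numeric(0)),
    n, frame_rate = frame_rate
  )
}

# fraction of analyzable frames whose four paw contact indicators all match
# the simulator ground truth
label_accuracy <- function(session, res) {
  tr <- res$tracks$load
  truth <- session$truth
  ana <- which(res$mask$analyzable)
  lm <- tr[ana, c("FL", "FR", "HL", "HR")] > 0
  tm <- as.matrix(truth[ana, c("load_FL", "load_FR", "load_HL",
                               "load_HR")]) > 0
  mean(rowSums(lm == tm) == 4L)
}

# per-identity Jaccard overlap of recovered vs true contact frames
contact_jaccard <- function(session, res, id) {
  ana <- which(res$mask$analyzable)
  a <- ana[res$tracks$load[ana, id] > 0]
  b <- ana[session$truth[[paste0("load_", id)]][ana] > 0]
  if (length(a) == 0L && length(b) == 0L) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

# independent repeated-measures ANOVA oracle via stats::aov error strata
oracle_rm_anova_F <- function(m) {
  df <- data.frame(
    y = as.vector(m),
    subject = factor(rep(seq_len(nrow(m)), ncol(m))),
    day = factor(rep(seq_len(ncol(m)), each = nrow(m)))
  )
  sm <- summary(stats::aov(y ~ day + Error(subject), data = df))
  tab <- sm[["Error: Within"]][[1]]
  c(F = tab[["F value"]][1], df1 = tab[["Df"]][1], df2 = tab[["Df"]][2],
    p = tab[["Pr(>F)"]][1])
}

# brute-force contact interval construction: split observed frames on gaps
# longer than max_gap
oracle_intervals <- function(frames, max_gap = 2L) {
  if (length(frames) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  frames <- sort(frames)
  brk <- which(diff(frames) > max_gap + 1L)
  starts <- frames[c(1L, brk + 1L)]
  ends <- frames[c(brk, length(frames))] + 1L
  data.frame(start = starts, end = ends)
}

# deterministic enumeration of small integer tables (entries 0..5) used to
# sweep the RM-ANOVA against the oracle
enumerate_tables <- function() {
  out <- list()
  k <- 0L
  for (n in 2:4) for (d in 2:4) for (rep_i in 1:4) {
    k <- k + 1L
    # fixed congruential pattern -> integer entries in 0..5
    idx <- seq_len(n * d)
    vals <- (7L * idx + 3L * rep_i + (idx * idx) %% 11L) %% 6L
    out[[k]] <- matrix(as.numeric(vals), n, d)
  }
  out
}
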