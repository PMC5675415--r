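paw_names <- c("FL", "FR", "HL", "HR")

test_that("stance_time_fractions counts loaded paws", {
  all4 <- make_tracks(matrix(25, 10, 4, dimnames = list(NULL, paw_names)))
  st <- stance_time_fractions(all4)
  expect_equal(unname(st["4"]), 100)
  expect_equal(sum(st), 100)

  half <- matrix(0, 10, 4, dimnames = list(NULL, paw_names))
  half[1:5, ] <- 25
  half[6:10, c("HL", "HR")] <- 50
  st2 <- stance_time_fractions(make_tracks(half))
  expect_equal(unname(st2[c("2", "4")]), c(50, 50))
  expect_equal(sum(st2), 100)
})

test_that("front_paw_contact_time is a per-paw percentage", {
  m <- matrix(0, 10, 4, dimnames = list(NULL, paw_names))
  m[, "FL"] <- 30
  m[1:3, "FR"] <- 30
  fp <- front_paw_contact_time(make_tracks(m))
  expect_equal(unname(fp), c(100, 30))
})

test_that("weight_distribution_axes uses contact-conditional means", {
  m <- matrix(rep(c(25, 25, 25, 25), each = 8), 8,
              dimnames = list(NULL, paw_names))
  wd <- weight_distribution_axes(make_tracks(m), body_weight = 100)
  expect_equal(unname(wd), c(50, 50, 50, 50))

  m2 <- matrix(rep(c(30, 30, 20, 20), each = 8), 8,
               dimnames = list(NULL, paw_names))
  wd2 <- weight_distribution_axes(make_tracks(m2), body_weight = 100)
  expect_equal(unname(wd2[c("front", "hind")]), c(60, 40))

  # a paw off the floor half the time keeps its conditional mean: rearing
  # does not deflate the front percentage
  m3 <- m2
  m3[1:4, c("FL", "FR")] <- 0
  wd3 <- weight_distribution_axes(make_tracks(m3), body_weight = 100)
  expect_equal(unname(wd3["front"]), 60)

  # tail/belly load shows up as front+hind just below 100: in pure
  # quadruped stance the complement is exactly the tail/belly fraction
  ph <- phenotype_params(rearing_rate = 0, wall_lean_rate = 0,
                         locomotion_rate = 0)
  s <- simulate_session(ph, sim_config(duration = 30, noise_sd = 0,
                                       seed = 11,
                                       tail_belly_load_fraction = 0.02))
  m <- analyze_session(s)$metrics
  expect_equal(m$pct_weight_front + m$pct_weight_hind, 98, tolerance = 1e-6)
  expect_equal(m$pct_weight_left + m$pct_weight_right, 98, tolerance = 1e-6)
})

test_that("barycenter reproduces the closed-form examples", {
  eq <- make_tracks(matrix(rep(c(25, 25, 25, 25), each = 4), 4,
                           dimnames = list(NULL, paw_names)))
  expect_equal(unname(barycenter(eq)), c(50, 50))

  # FR = 30, HR = 30, FL = 20, HL = 20 -> PRP 60, PFP 50
  m <- matrix(rep(c(20, 30, 20, 30), each = 4), 4,
              dimnames = list(NULL, paw_names))
  for (method in c("contact_means", "ratio_of_sums", "mean_of_ratios")) {
    bc <- barycenter(make_tracks(m), method = method)
    expect_equal(unname(bc), c(60, 50))
  }
})

test_that("complementarity identities hold exactly", {
  set.seed(7)
  for (rep_i in 1:10) {
    m <- matrix(stats::runif(40, 0, 120), 10, 4,
                dimnames = list(NULL, paw_names))
    m[sample(40, 8)] <- 0
    tr <- make_tracks(m)
    for (method in c("contact_means", "ratio_of_sums", "mean_of_ratios")) {
      bc <- barycenter(tr, method = method)
      mirror <- m[, c("FR", "FL", "HR", "HL")]
      colnames(mirror) <- paw_names
      bc_m <- barycenter(make_tracks(mirror), method = method)
      expect_equal(unname(bc["PRP"] + bc_m["PRP"]), 100) # PRP + PLP
      flip <- m[, c("HL", "HR", "FL", "FR")]
      colnames(flip) <- paw_names
      bc_f <- barycenter(make_tracks(flip), method = method)
      expect_equal(unname(bc["PFP"] + bc_f["PFP"]), 100) # PFP + PHP
    }
  }
})

test_that("restriction property: masking equals deleting excluded frames", {
  set.seed(8)
  m <- matrix(stats::runif(48, 10, 100), 12, 4,
              dimnames = list(NULL, paw_names))
  m[2, "FL"] <- 0
  keep <- c(1:4, 7:10)
  mask <- full_mask(12)
  mask$analyzable[setdiff(1:12, keep)] <- FALSE
  mask$analyzed_time <- length(keep) / mask$frame_rate
  tr_all <- make_tracks(m)
  tr_sub <- make_tracks(m[keep, , drop = FALSE])
  expect_equal(stance_time_fractions(tr_all, mask),
               stance_time_fractions(tr_sub))
  expect_equal(front_paw_contact_time(tr_all, mask),
               front_paw_contact_time(tr_sub))
  expect_equal(weight_distribution_axes(tr_all, mask, 300),
               weight_distribution_axes(tr_sub, body_weight = 300))
  expect_equal(barycenter(tr_all, mask), barycenter(tr_sub))
})

test_that("degenerate paw loads signal instead of returning numbers", {
  zero <- make_tracks(matrix(0, 5, 4, dimnames = list(NULL, paw_names)))
  expect_error(barycenter(zero), "no paw-borne weight")
  st <- stance_time_fractions(zero)
  expect_equal(unname(st["0"]), 100)
})

test_that("summarize_session assembles a consistent row", {
  s <- quick_session("D0", seed = 12, duration = 20)
  res <- analyze_session(s)
  m <- res$metrics
  expect_s3_class(m, "session_metrics")
  expect_identical(m$day, "D0")
  expect_true(m$analyzable)
  expect_equal(
    m$pct_time_on_0 + m$pct_time_on_1 + m$pct_time_on_2 +
      m$pct_time_on_3 + m$pct_time_on_4, 100
  )
  # per-field brute-force recomputation from the track table
  tr <- res$tracks
  mask <- res$mask
  ana <- which(mask$analyzable)
  expect_equal(m$pct_time_FL, mean(tr$load[ana, "FL"] > 0) * 100)
  expect_equal(m$analyzed_time, length(ana) / 30)
  fl <- tr$load[ana, "FL"]; fr <- tr$load[ana, "FR"]
  hl <- tr$load[ana, "HL"]; hr <- tr$load[ana, "HR"]
  cmean <- function(v) if (any(v > 0)) mean(v[v > 0]) else 0
  expect_equal(m$pct_weight_front, (cmean(fl) + cmean(fr)) / 300 * 100)
  W <- c(cmean(fl), cmean(fr), cmean(hl), cmean(hr))
  expect_equal(m$PRP, (W[2] + W[4]) / sum(W) * 100)
  expect_equal(m$PFP, (W[1] + W[2]) / sum(W) * 100)

  # fully excluded session yields flagged NA metrics
  mask0 <- full_mask(tr$n_frames)
  mask0$analyzable[] <- FALSE
  m0 <- summarize_session(tr, mask0, meta = list(body_weight = 300))
  expect_false(m0$analyzable)
  expect_true(is.na(m0$PRP))
})

test_that("symmetric sessions balance left/right outcomes", {
  s <- quick_session("D0", seed = 13, duration = 120)
  m <- analyze_session(s)$metrics
  expect_lt(abs(m$pct_time_FL - m$pct_time_FR), 3)
  expect_lt(abs(m$PRP - 50), 1.5)
})
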