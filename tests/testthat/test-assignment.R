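blob_row <- function(load, x, y, n_cells = 4L, elongation = 1) {
  data.frame(frame = 1L, blob = NA_integer_, load = load, x = x, y = y,
             n_cells = n_cells, touches_wall = FALSE, elongation = elongation)
}

test_that("estimate_body_pose centroids and heading carry-over", {
  p1 <- estimate_body_pose(blob_row(100, 10, 10))
  expect_equal(c(p1$x, p1$y), c(10, 10))
  p2 <- estimate_body_pose(rbind(blob_row(50, 8, 10), blob_row(50, 12, 10)))
  expect_equal(c(p2$x, p2$y), c(10, 10))
  expect_null(estimate_body_pose(blob_row(10, 1, 1)[0, ]))

  # stationary history: heading carried from the last defined pose
  hist <- list(x = rep(10, 30), y = rep(10, 30),
               heading_x = rep(0.6, 30), heading_y = rep(0.8, 30))
  p3 <- estimate_body_pose(blob_row(100, 10, 10), history = hist)
  expect_equal(p3$heading, c(0.6, 0.8))
  expect_false(p3$heading_defined)

  # sustained displacement defines the heading along the movement
  hist2 <- list(x = seq(5, 10.8, by = 0.2)[1:30], y = rep(10, 30),
                heading_x = rep(0, 30), heading_y = rep(1, 30))
  p4 <- estimate_body_pose(blob_row(100, 11, 10), history = hist2)
  expect_true(p4$heading_defined)
  expect_equal(p4$heading, c(1, 0), tolerance = 1e-6)
})

test_that("quadrant rule labels four symmetric blobs", {
  blobs <- rbind(
    blob_row(50, 12.5 - 3, 12.5 + 4), # front-left of centre
    blob_row(50, 12.5 + 3, 12.5 + 4),
    blob_row(60, 12.5 - 3, 12.5 - 4),
    blob_row(60, 12.5 + 3, 12.5 - 4)
  )
  pose <- estimate_body_pose(blobs)
  lab <- classify_blobs(blobs, pose, prior_heading = c(0, 1))
  expect_false(attr(lab, "ambiguous"))
  expect_identical(lab$identity, c("FL", "FR", "HL", "HR"))
})

test_that("a lone lateral pair is read as rearing hind paws", {
  blobs <- rbind(blob_row(150, 10.5, 12), blob_row(150, 14.5, 12))
  pose <- estimate_body_pose(blobs)
  lab <- classify_blobs(blobs, pose, prior_heading = c(0, 1))
  expect_setequal(lab$identity, c("HL", "HR"))
  expect_identical(lab$identity[1], "HL") # x smaller = left when facing +y
})

test_that("mirroring across the body axis swaps left/right only", {
  blobs <- rbind(
    blob_row(55, 12.5 - 1.8, 12.5 + 3.5),
    blob_row(45, 12.5 + 1.8, 12.5 + 3.5),
    blob_row(110, 12.5 - 2.2, 12.5 - 2.5),
    blob_row(100, 12.5 + 2.2, 12.5 - 2.5)
  )
  pose <- estimate_body_pose(blobs)
  lab <- classify_blobs(blobs, pose, prior_heading = c(0, 1))
  mirrored <- blobs
  mirrored$x <- 25 - mirrored$x # mirror across the vertical body axis
  pose_m <- estimate_body_pose(mirrored)
  lab_m <- classify_blobs(mirrored, pose_m, prior_heading = c(0, 1))
  swap <- c(FL = "FR", FR = "FL", HL = "HR", HR = "HL")
  expect_identical(unname(swap[lab$identity]), lab_m$identity)
})

test_that("belly and tail blobs are recognised and never duplicated", {
  blobs <- rbind(
    blob_row(40, 12.5 - 1.8, 12.5 + 3.5),
    blob_row(40, 12.5 + 1.8, 12.5 + 3.5),
    blob_row(100, 12.5 - 2.2, 12.5 - 2.5),
    blob_row(100, 12.5 + 2.2, 12.5 - 2.5),
    blob_row(12, 12.2, 11.6, n_cells = 9L),            # central belly
    blob_row(8, 12.5, 12.5 - 6, n_cells = 6L, elongation = 6) # trailing tail
  )
  pose <- estimate_body_pose(blobs)
  lab <- classify_blobs(blobs, pose, prior_heading = c(0, 1))
  expect_identical(lab$identity[5], "BELLY")
  expect_identical(lab$identity[6], "TAIL")
  ids <- lab$identity[!is.na(lab$identity)]
  expect_false(anyDuplicated(ids) > 0)
})

test_that("competing candidates flag the frame ambiguous", {
  blobs <- rbind(
    blob_row(50, 10, 16), blob_row(50, 15, 16),
    blob_row(50, 10, 9), blob_row(50, 15, 9),
    blob_row(50, 12.5, 16.5) # fifth paw-sized blob
  )
  pose <- estimate_body_pose(blobs)
  lab <- classify_blobs(blobs, pose, prior_heading = c(0, 1))
  expect_true(attr(lab, "ambiguous"))
  expect_true(all(is.na(lab$identity) | lab$identity %in% c("BELLY", "TAIL")))
})

test_that("link_tracks applies the gap-bridging rule", {
  mk_labels <- function(frames) {
    data.frame(frame = frames, identity = "FL", load = 50,
               x = 10, y = 10)
  }
  # present every frame -> a single full interval
  t1 <- link_tracks(mk_labels(1:20), 20L)
  expect_identical(t1$intervals$start, 1L)
  expect_identical(t1$intervals$end, 21L)

  # gap of two frames (11, 12 missing) is bridged with interpolated load
  lab <- mk_labels(c(1:10, 13:21))
  lab$load[lab$frame == 10] <- 30
  lab$load[lab$frame == 13] <- 60
  t2 <- link_tracks(lab, 21L)
  expect_identical(nrow(t2$intervals), 1L)
  expect_identical(c(t2$intervals$start, t2$intervals$end), c(1L, 22L))
  expect_equal(t2$load[11:12, "FL"], c(40, 50))

  # gap of five frames splits the contact
  t3 <- link_tracks(mk_labels(c(1:10, 16:21)), 21L)
  expect_identical(nrow(t3$intervals), 2L)
  expect_identical(t3$intervals$start, c(1L, 16L))
  expect_identical(t3$intervals$end, c(11L, 22L))

  # centroid jumps beyond the gate split even adjacent frames
  lab4 <- mk_labels(1:10)
  lab4$x[6:10] <- 20
  t4 <- link_tracks(lab4, 10L)
  expect_identical(nrow(t4$intervals), 2L)
})

test_that("link_tracks matches the brute-force interval oracle", {
  set.seed(42)
  for (rep_i in 1:20) {
    frames <- sort(sample(1:60, 25))
    got <- link_tracks(
      data.frame(frame = frames, identity = "HR", load = 80, x = 5, y = 5),
      60L
    )$intervals
    want <- oracle_intervals(frames)
    expect_identical(got$start, want$start)
    expect_identical(got$end, want$end)
  }
})

test_that("straight 3 cm/s locomotion yields a heading within 10 degrees", {
  # four-paw layout translating along +y at 0.1 cm per frame (3 cm/s)
  step <- 3 / 30
  frames <- lapply(1:60, function(i) {
    y0 <- 6 + step * i
    rbind(
      blob_row(40, 12.5 - 1.8, y0 + 3.5), blob_row(40, 12.5 + 1.8, y0 + 3.5),
      blob_row(110, 12.5 - 2.2, y0 - 2.5), blob_row(110, 12.5 + 2.2, y0 - 2.5)
    )
  })
  blobs <- do.call(rbind, Map(function(fb, i) {
    fb$frame <- i; fb
  }, frames, seq_along(frames)))
  asg <- assign_session(blobs, 60L)
  tp <- asg$poses[31:60, ]
  ang <- acos(pmin(1, tp$heading_y)) * 180 / pi
  expect_true(all(ang < 10))
  expect_true(all(tp$heading_x == 0))
})

test_that("noise-free end-to-end labels and intervals match ground truth", {
  s <- quick_session("D0", seed = 9, duration = 60)
  res <- analyze_session(s)
  expect_gte(label_accuracy(s, res), 0.99)
  for (p in c("FL", "FR", "HL", "HR")) {
    expect_gte(contact_jaccard(s, res, p), 0.95)
  }
})
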