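test_that("zero-motion video: propagation and tracking are identities", {
  v <- static_video(seed = 2, n = 8L)
  seg <- segment_fasciae(v$frames[[1]], frame_index = 1L)
  segs <- propagate_segmentation(v, seg)
  for (t in 2:8) {
    expect_identical(segs[[t]]$source, "propagated")
    expect_equal(segs[[t]]$boundaries, seg$boundaries, tolerance = 1e-9)
  }
  pts <- place_measurement_points(seg)
  tracks <- track_points(v, pts)
  for (t in 2:8) {
    sub <- tracks[tracks$frame == t, ]
    expect_equal(sub$row, pts$row, tolerance = 1e-9)
    expect_equal(sub$col, pts$col, tolerance = 1e-9)
  }
})

test_that("rigid translation is recovered within 0.5 px", {
  # axial drift +1 px/frame over 12 frames
  s <- small_script(n_frames = 12L, phase_frames = c(2L, 3L, 10L, 11L),
                    rest_thickness = c(OE = 5, OI = 9, TrA = 4.6),
                    contracted_thickness = c(OE = 5, OI = 9, TrA = 4.6),
                    drift = c(lateral = 0, axial = 1))
  g <- generate_video(s, seed = 13)
  v <- g$video
  seg0 <- fascia_segmentation(1L, g$truth$boundaries[[1]],
                              img_dim = dim(v$frames[[1]]),
                              source = "automatic")
  segs <- propagate_segmentation(v, seg0)
  for (t in c(4L, 8L, 12L)) {
    err <- abs(segs[[t]]$boundaries - g$truth$boundaries[[t]])
    expect_lt(max(err), 0.5)
  }
  pts <- place_measurement_points(seg0)
  tracks <- track_points(v, pts)
  for (t in c(4L, 8L, 12L)) {
    sub <- tracks[tracks$frame == t, ]
    expect_true(all(abs(sub$row - (pts$row + (t - 1))) < 0.5))
    expect_true(all(abs(sub$col - pts$col) < 0.5))
  }
})

test_that("integer-shifting the whole video shifts all outputs equally", {
  v <- static_video(seed = 6, n = 4L)
  dy <- 3L
  shifted_frames <- lapply(v$frames, function(f) {
    g <- f[c((dy + 1):nrow(f), rep(nrow(f), dy)), ]
    g
  })
  vs <- ultrasound_video(shifted_frames, v$pixel_spacing, v$frame_rate)
  seg <- segment_fasciae(v$frames[[1]], frame_index = 1L)
  seg_s <- segment_fasciae(vs$frames[[1]], frame_index = 1L)
  expect_lt(max(abs(seg_s$boundaries - (seg$boundaries - dy))), 0.5)
})

test_that("reference-frame selection equals brute-force correlation", {
  set.seed(33)
  frames <- lapply(1:15, function(i) matrix(runif(400, 0, 255), 20, 20))
  v <- ultrasound_video(frames, 0.1)
  # current frame = noisy copy of frame 12
  v$frames[[15]] <- frames[[12]] + matrix(rnorm(400, 0, 5), 20, 20)
  candidates <- c(2L, 5L, 9L, 12L, 14L)
  picked <- select_reference_frame(v, 15L, candidates)
  brute <- candidates[which.max(vapply(candidates, function(k)
    stats::cor(as.vector(v$frames[[15]]), as.vector(v$frames[[k]])),
    numeric(1)))]
  expect_identical(picked, brute)
  expect_identical(picked, 12L)

  expect_identical(select_reference_frame(v, 3L, 7L), 7L)  # singleton
  expect_identical(select_reference_frame(v, 12L, candidates), 12L)
  flat <- ultrasound_video(rep(list(matrix(1, 8, 8)), 3), 0.1)
  expect_error(select_reference_frame(flat, 1L, 2L), "zero-variance")
  expect_error(select_reference_frame(v, 1L, integer()), "empty")
})

test_that("measurement points sit on the upper fasciae at 40/50/60%", {
  b <- rbind(rep(50, 100), rep(80, 100), rep(120, 100), rep(160, 100))
  seg <- fascia_segmentation(1L, b, img_dim = c(200L, 100L))
  pts <- place_measurement_points(seg)
  expect_identical(nrow(pts), 9L)
  oe <- pts[pts$muscle == "OE", ]
  expect_equal(oe$row, rep(50, 3))
  expect_equal(oe$col, c(41, 51, 61))  # 0-based 40/50/60 of [0, 100)
  expect_equal(pts[pts$muscle == "OI", "row"], rep(80, 3))
  expect_equal(pts[pts$muscle == "TrA", "row"], rep(120, 3))

  # apex at the middle column is hit by the middle point
  tri <- 100 - 20 * abs(seq_len(100) - 51) / 50
  b2 <- rbind(tri, tri + 30, tri + 60, tri + 90)
  seg2 <- fascia_segmentation(1L, b2, img_dim = c(200L, 100L))
  mid <- place_measurement_points(seg2)
  expect_equal(mid[mid$muscle == "OE" & mid$point_id == 1, "row"],
               max(tri))

  # sinusoidal polyline rows equal independent interpolation
  sine <- 60 + 5 * sin(seq_len(100) / 7)
  b3 <- rbind(sine, sine + 30, sine + 60, sine + 90)
  seg3 <- fascia_segmentation(1L, b3, img_dim = c(200L, 100L))
  p3 <- place_measurement_points(seg3)
  cols <- c(41, 51, 61)
  expect_equal(p3[p3$muscle == "OE", "row"],
               stats::approx(seq_len(100), sine, xout = cols)$y)

  narrow <- fascia_segmentation(1L, b[, 1:3], img_dim = c(200L, 100L))
  expect_error(place_measurement_points(narrow), "column range")
})

test_that("points initialized outside the image are rejected", {
  v <- static_video(seed = 3, n = 3L)
  seg <- segment_fasciae(v$frames[[1]], frame_index = 1L)
  pts <- place_measurement_points(seg)
  pts$row[1] <- -5
  expect_error(track_points(v, pts), "outside the image")
})

test_that("tracks CSV round trip keeps 1-based R indices consistent", {
  v <- static_video(seed = 4, n = 3L)
  seg <- segment_fasciae(v$frames[[1]], frame_index = 1L)
  tracks <- track_points(v, place_measurement_points(seg))
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks_csv(tracks, path)
  raw <- utils::read.csv(path)
  expect_identical(min(raw$frame), 0L)  # 0-based on disk
  back <- read_tracks_csv(path)
  expect_equal(back$row, tracks$row)
  expect_equal(back$frame, tracks$frame)
})
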