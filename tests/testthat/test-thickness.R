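flat_seg <- function(rows = c(10, 20, 35, 50), w = 60L, nr = 100L) {
  fascia_segmentation(1L, do.call(rbind, lapply(rows, rep, w)),
                      img_dim = c(nr, w))
}

test_that("thickness is vertical distance times pixel spacing", {
  seg <- flat_seg()
  expect_equal(thickness_at_point(seg, "OE", c(10, 30), 0.1), 1.0)
  expect_equal(thickness_at_point(seg, "OI", c(20, 30), 0.1), 1.5)
  # calibration linearity: doubling the spacing doubles the thickness
  expect_equal(thickness_at_point(seg, "TrA", c(35, 30), 0.2),
               2 * thickness_at_point(seg, "TrA", c(35, 30), 0.1))
  expect_error(thickness_at_point(seg, "OE", c(10, 500), 0.1),
               "column range")
  expect_error(thickness_at_point(seg, "OE", c(25, 30), 0.1), "crossing")
  expect_error(thickness_at_point(seg, "XX", c(10, 30), 0.1), "muscle")
})

test_that("traces on a static video are constant and calibrated", {
  v <- static_video(seed = 8, n = 25L)
  m_seg <- segment_fasciae(v$frames[[1]], frame_index = 1L)
  segs <- propagate_segmentation(v, m_seg)
  tracks <- track_points(v, place_measurement_points(m_seg))
  trace <- build_traces(segs, tracks, v)
  expect_s3_class(trace, "thickness_trace")
  for (m in c("OE", "OI", "TrA")) {
    tm <- muscle_mean_trace(trace, m)
    expect_lt(diff(range(tm)), 0.05)
  }
  expect_equal(trace$time_s, (trace$frame - 1) / 30)
})

test_that("flagged points become missing values, others survive", {
  v <- static_video(seed = 8, n = 25L)
  m_seg <- segment_fasciae(v$frames[[1]], frame_index = 1L)
  segs <- propagate_segmentation(v, m_seg)
  tracks <- track_points(v, place_measurement_points(m_seg))
  tracks$flag[tracks$frame == 3 & tracks$muscle == "TrA" &
                tracks$point_id == 0] <- "lost"
  trace <- build_traces(segs, tracks, v)
  sub <- trace[trace$frame == 3 & trace$muscle == "TrA", ]
  expect_identical(sum(is.na(sub$thickness_mm)), 1L)
  expect_false(is.na(muscle_mean_trace(trace, "TrA")[3]))

  # a muscle missing on most frames aborts with its name
  tracks$flag[tracks$muscle == "OI"] <- "lost"
  expect_error(build_traces(segs, tracks, v), "OI")
})

test_that("a noise-free step is detected at its exact frames", {
  vals <- rep(4.6, 100); vals[41:80] <- 5.4  # 0-based [40, 80)
  trace <- make_trace(list(OE = rep(5, 100), OI = rep(9, 100), TrA = vals))
  ph <- detect_contraction_phase(trace)
  expect_identical(ph$contracted[[1]], c(41L, 80L))
  expect_identical(ph$rest[[1]], c(1L, 40L))
  expect_identical(ph$rest[[2]], c(81L, 100L))
})

test_that("phase detection ignores a constant offset and flat traces", {
  vals <- rep(4.6, 100); vals[41:80] <- 5.4
  t1 <- make_trace(list(OE = rep(5, 100), OI = rep(9, 100), TrA = vals))
  t2 <- make_trace(list(OE = rep(5, 100), OI = rep(9, 100),
                        TrA = vals + 2.5))
  expect_identical(detect_contraction_phase(t1)$contracted,
                   detect_contraction_phase(t2)$contracted)

  flat <- make_trace(list(OE = rep(5, 100), OI = rep(9, 100),
                          TrA = rep(4.6, 100)))
  expect_warning(ph <- detect_contraction_phase(flat), "no contraction")
  expect_length(ph$contracted, 0)

  short <- make_trace(list(OE = rep(5, 10), OI = rep(9, 10),
                           TrA = rep(4.6, 10)))
  expect_error(detect_contraction_phase(short), "20 frames")
})

test_that("phase summaries average points first, then frames", {
  vals <- rep(4.6, 100); vals[41:80] <- 5.4
  trace <- make_trace(list(OE = rep(5, 100), OI = rep(9, 100), TrA = vals))
  ph <- detect_contraction_phase(trace)
  sm <- summarize_phases(trace, ph)
  expect_equal(sm$rest_mm[sm$muscle == "TrA"], 4.6)
  expect_equal(sm$contracted_mm[sm$muscle == "TrA"], 5.4)
  expect_equal(sm$rest_mm[sm$muscle == "OE"], 5)
  expect_equal(sm$contracted_mm[sm$muscle == "OE"], 5)

  const <- make_trace(list(OE = rep(5, 100), OI = rep(5, 100),
                           TrA = rep(5, 100)))
  sm2 <- summarize_phases(const, ph)
  expect_equal(sm2$rest_mm, rep(5, 3))
  expect_equal(sm2$contracted_mm, rep(5, 3))

  # pooling pre+post rest frames is available as an option
  sm3 <- summarize_phases(trace, ph, rest_mode = "all")
  expect_equal(sm3$n_rest_frames[sm3$muscle == "TrA"], 60)
  expect_equal(sm$n_rest_frames[sm$muscle == "TrA"], 40)
})

test_that("scripted contraction end-to-end trace follows the script", {
  s <- contraction_script()  # full resolution: 0.1 mm/px
  g <- generate_video(s, seed = 19)
  m <- measure_video(g$video)
  tra <- muscle_mean_trace(m$trace, "TrA")
  truth <- g$truth$thickness_mm[, "TrA"]
  expect_lt(stats::median(abs(tra - truth)), 0.1)
  # detected contraction overlaps the true contracted frames well
  det <- seq.int(m$phases$contracted[[1]][1], m$phases$contracted[[1]][2])
  tru <- which(g$truth$phase == "contracted")
  jac <- length(intersect(det, tru)) / length(union(det, tru))
  expect_gte(jac, 0.6)
  expect_lt(abs(m$par - g$truth$par), 0.01)
})
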