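#' Thickness of one muscle at a tracked point
#'
#' Thickness is measured vertically (down the image column through the
#' tracked point on the muscle's upper fascia) to the muscle's lower
#' boundary, then calibrated to millimetres. Vertical distance is the
#' usual rehabilitative-ultrasound convention and is well defined for
#' polyline boundaries.
#'
#' @param segmentation a [fascia_segmentation] for the point's frame.
#' @param muscle `"OE"`, `"OI"` or `"TrA"`.
#' @param point numeric `(row, col)`, 1-based image coordinates.
#' @param pixel_spacing calibration in mm/pixel.
#' @return thickness in mm (> 0).
#' @export
thickness_at_point <- function(segmentation, muscle, point, pixel_spacing) {
  m <- match(muscle, MUSCLES)
  if (is.na(m)) stop("unknown muscle: ", muscle)
  b <- segmentation$boundaries
  local_col <- point[2] - segmentation$col_start + 1
  if (local_col < 1 || local_col > ncol(b))
    stop("point outside the segmented column range")
  lower <- polyline_interp(b[m + 1, ], local_col)
  px <- lower - point[1]
  if (px <= 0)
    stop("lower boundary lies above the measurement point (crossing)")
  px * pixel_spacing
}

#' Build calibrated thickness traces from segmentations and tracks
#'
#' Combines the per-frame segmentations (lower boundaries) with the
#' tracked measurement points (upper-fascia positions) into one
#' thickness value per (frame, muscle, point). Flagged (lost) points are
#' carried as missing values, never dropped.
#'
#' @param segmentations list of per-frame [fascia_segmentation]s.
#' @param tracks data.frame from [track_points()].
#' @param video the source [ultrasound_video] (for calibration and
#'   frame rate).
#' @param max_missing_fraction a muscle whose every point is missing on
#'   more than this fraction of frames aborts the trace (default 0.5).
#' @return data.frame of class `thickness_trace`: `frame`, `time_s`,
#'   `muscle`, `point_id`, `thickness_mm`, `flag`, with the pixel
#'   spacing attached as attribute `pixel_spacing`.
#' @export
build_traces <- function(segmentations, tracks, video,
                         max_missing_fraction = 0.5) {
  nf <- n_frames(video)
  if (length(segmentations) != nf)
    stop("need one segmentation per frame (got ", length(segmentations),
         " for ", nf, " frames)")
  fr <- video$frame_rate
  th <- numeric(nrow(tracks))
  for (i in seq_len(nrow(tracks))) {
    if (tracks$flag[i] != "ok") { th[i] <- NA_real_; next }
    th[i] <- tryCatch(
      thickness_at_point(segmentations[[tracks$frame[i]]],
                         tracks$muscle[i],
                         c(tracks$row[i], tracks$col[i]),
                         video$pixel_spacing),
      error = function(e) NA_real_)
  }
  out <- data.frame(
    frame = tracks$frame,
    time_s = if (is.null(fr)) NA_real_ else (tracks$frame - 1) / fr,
    muscle = tracks$muscle, point_id = tracks$point_id,
    thickness_mm = th,
    flag = ifelse(is.na(th), "missing", "ok"))
  for (m in MUSCLES) {
    sub <- out[out$muscle == m, ]
    valid_frames <- tapply(!is.na(sub$thickness_mm), sub$frame, any)
    if (mean(valid_frames) < 1 - max_missing_fraction)
      stop("muscle ", m, " has no valid measurement point on more than ",
           round(100 * max_missing_fraction), "% of frames")
  }
  attr(out, "pixel_spacing") <- video$pixel_spacing
  class(out) <- c("thickness_trace", "data.frame")
  out
}

#' Per-frame mean thickness of one muscle over its measurement points
#' @param trace a `thickness_trace`.
#' @param muscle muscle name.
#' @return numeric vector indexed by frame (NA where no point is valid).
#' @export
muscle_mean_trace <- function(trace, muscle) {
  sub <- trace[trace$muscle == muscle, ]
  nf <- max(trace$frame)
  v <- rep(NA_real_, nf)
  agg <- tapply(sub$thickness_mm, sub$frame, mean, na.rm = TRUE)
  v[as.integer(names(agg))] <- as.numeric(agg)
  v[is.nan(v)] <- NA_real_
  v
}

moving_median <- function(x, width = 5L) {
  h <- (width - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i)
    stats::median(x[max(1L, i - h):min(n, i + h)], na.rm = TRUE),
    numeric(1))
}

#' Detect the contraction phase on a thickness trace
#'
#' The three-point mean thickness of the target muscle (TrA by default)
#' is smoothed with a moving median; the baseline is the median of the
#' first `baseline_fraction` of frames. The contracted interval is the
#' longest run that starts where the smoothed trace reaches
#' `baseline + enter_fraction * (peak - baseline)` and continues while
#' it stays above the hysteresis exit level
#' `baseline + exit_fraction * (peak - baseline)`. Rest is the frames
#' before entry and after exit.
#'
#' @param trace a `thickness_trace` (>= 20 frames).
#' @param muscle muscle on which detection runs (default `"TrA"`, the
#'   muscle whose thickening defines the draw-in maneuver).
#' @param baseline_fraction fraction of initial frames defining the
#'   baseline (default 0.15).
#' @param smooth_window moving-median width in frames (default 5).
#' @param enter_fraction,exit_fraction entry/exit thresholds as a
#'   fraction of (peak - baseline) (defaults 0.5 / 0.3).
#' @return object of class `phase_annotation`: `contracted` (list of
#'   1-based inclusive `c(start, end)` intervals, possibly empty),
#'   `rest` (list of intervals), `params` echo. A flat trace yields an
#'   empty contracted interval with a warning, not an error.
#' @export
detect_contraction_phase <- function(trace, muscle = "TrA",
                                     baseline_fraction = 0.15,
                                     smooth_window = 5L,
                                     enter_fraction = 0.5,
                                     exit_fraction = 0.3) {
  v <- muscle_mean_trace(trace, muscle)
  n <- length(v)
  if (n < 20L) stop("contraction detection needs at least 20 frames")
  sm <- moving_median(v, smooth_window)
  nb <- max(1L, ceiling(baseline_fraction * n))
  baseline <- stats::median(sm[seq_len(nb)], na.rm = TRUE)
  peak <- max(sm, na.rm = TRUE)
  params <- list(muscle = muscle, baseline_fraction = baseline_fraction,
                 smooth_window = smooth_window,
                 enter_fraction = enter_fraction,
                 exit_fraction = exit_fraction,
                 baseline = baseline, peak = peak)
  empty <- structure(list(contracted = list(),
                          rest = list(c(1L, n)), params = params),
                     class = "phase_annotation")
  if (!is.finite(peak) || peak <= baseline) {
    warning("no contraction detected (peak <= baseline)")
    return(empty)
  }
  hi <- baseline + enter_fraction * (peak - baseline)
  lo <- baseline + exit_fraction * (peak - baseline)
  runs <- list()
  state <- FALSE; start <- NA_integer_
  for (i in seq_len(n)) {
    x <- sm[i]
    if (!state && !is.na(x) && x >= hi) { state <- TRUE; start <- i }
    else if (state && (!is.na(x) && x < lo)) {
      runs[[length(runs) + 1L]] <- c(start, i - 1L); state <- FALSE
    }
  }
  if (state) runs[[length(runs) + 1L]] <- c(start, n)
  if (!length(runs)) {
    warning("no contraction detected (threshold never reached)")
    return(empty)
  }
  lengths <- vapply(runs, function(r) r[2] - r[1] + 1L, integer(1))
  contracted <- runs[[which.max(lengths)]]
  rest <- list()
  if (contracted[1] > 1L) rest[[1]] <- c(1L, contracted[1] - 1L)
  if (contracted[2] < n) rest[[length(rest) + 1L]] <- c(contracted[2] + 1L, n)
  structure(list(contracted = list(contracted), rest = rest,
                 params = params),
            class = "phase_annotation")
}

phase_frames_of <- function(intervals) {
  if (!length(intervals)) return(integer())
  unlist(lapply(intervals, function(r) seq.int(r[1], r[2])))
}

#' Rest and contracted thickness summaries per muscle
#'
#' For each muscle, the three measurement points are averaged per frame
#' first, then the per-frame means are averaged over each phase's
#' frames, giving one rest and one contracted thickness per muscle (the
#' OE_R ... TrA_C quantities that enter the PAR).
#'
#' @param trace a `thickness_trace`.
#' @param phases a `phase_annotation`.
#' @param rest_mode `"pre"` (default): rest = frames before the
#'   contraction only; `"all"`: pool pre- and post-contraction rest.
#' @param min_valid_fraction minimum fraction of phase frames with a
#'   valid value (default 0.5); below it the summary errors.
#' @return data.frame: `muscle`, `rest_mm`, `contracted_mm`,
#'   `n_rest_frames`, `n_contracted_frames`.
#' @export
summarize_phases <- function(trace, phases, rest_mode = c("pre", "all"),
                             min_valid_fraction = 0.5) {
  rest_mode <- match.arg(rest_mode)
  if (!length(phases$contracted))
    stop("empty contracted phase: nothing to summarize")
  contracted_f <- phase_frames_of(phases$contracted)
  rest_iv <- phases$rest
  if (rest_mode == "pre" && length(rest_iv) > 1L) {
    pre <- Filter(function(r) r[2] < phases$contracted[[1]][1], rest_iv)
    if (length(pre)) rest_iv <- pre
  }
  rest_f <- phase_frames_of(rest_iv)
  if (!length(rest_f)) stop("empty rest phase: nothing to summarize")
  out <- do.call(rbind, lapply(MUSCLES, function(m) {
    v <- muscle_mean_trace(trace, m)
    for (fr in list(rest_f, contracted_f)) {
      if (mean(!is.na(v[fr])) < min_valid_fraction)
        stop("muscle ", m, " has fewer than ",
             round(100 * min_valid_fraction),
             "% valid frames in a phase")
    }
    data.frame(muscle = m,
               rest_mm = mean(v[rest_f], na.rm = TRUE),
               contracted_mm = mean(v[contracted_f], na.rm = TRUE),
               n_rest_frames = sum(!is.na(v[rest_f])),
               n_contracted_frames = sum(!is.na(v[contracted_f])))
  }))
  rownames(out) <- NULL
  out
}

#' Write a thickness trace / phase annotation to disk
#'
#' CSV frame indices are 0-based on disk; the phase JSON uses 0-based
#' half-open intervals.
#'
#' @param trace a `thickness_trace`.
#' @param phases a `phase_annotation`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  out <- as.data.frame(trace)
  out$frame <- out$frame - 1L
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
write_phases_json <- function(phases, path) {
  iv0 <- function(ivs) lapply(ivs, function(r) c(r[1] - 1L, r[2]))
  jsonlite::write_json(
    list(rest = iv0(phases$rest), contracted = iv0(phases$contracted),
         params = phases$params),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
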