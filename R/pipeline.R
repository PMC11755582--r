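#' Measure one video end-to-end
#'
#' The complete measurement chain on a single recording: initial-frame
#' selection (highest Sobel edge energy), Viterbi fascia segmentation,
#' optional operator correction, optical-flow propagation to all frames,
#' Lucas-Kanade tracking of the nine measurement points, calibrated
#' thickness traces, contraction-phase detection on the TrA, phase
#' summaries and the PAR.
#'
#' @param video an [ultrasound_video].
#' @param viterbi a [viterbi_config].
#' @param tracker a [tracker_config].
#' @param correction optional correction (see [apply_correction()]).
#' @param extra_keyframes optional further frame indices to segment and
#'   use as additional tracking keyframes (stabilizes difficult videos).
#' @param rest_mode passed to [summarize_phases()].
#' @param phase_params named list overriding
#'   [detect_contraction_phase()] defaults.
#' @return list with `initial_frame`, `segmentation` (the corrected
#'   initial segmentation), `segmentations` (per frame), `points`,
#'   `tracks`, `trace`, `phases`, `summary` (per-muscle rest/contracted
#'   mm) and `par`.
#' @export
measure_video <- function(video, viterbi = viterbi_config(),
                          tracker = tracker_config(),
                          correction = NULL, extra_keyframes = integer(),
                          rest_mode = "pre", phase_params = list()) {
  f0 <- select_initial_frame(video)
  seg0 <- segment_fasciae(video$frames[[f0]], viterbi, frame_index = f0)
  if (!is.null(correction)) seg0 <- apply_correction(seg0, correction)
  keyframes <- list(seg0)
  for (kf in setdiff(as.integer(extra_keyframes), f0))
    keyframes[[length(keyframes) + 1L]] <-
      segment_fasciae(video$frames[[kf]], viterbi, frame_index = kf)
  segs <- propagate_segmentation(video, keyframes, tracker)
  points <- lapply(keyframes, place_measurement_points)
  tracks <- track_points(video, points, tracker)
  trace <- build_traces(segs, tracks, video)
  phases <- do.call(detect_contraction_phase,
                    c(list(trace = trace), phase_params))
  summary <- summarize_phases(trace, phases, rest_mode = rest_mode)
  list(initial_frame = f0, segmentation = seg0, segmentations = segs,
       points = points[[1]], tracks = tracks, trace = trace,
       phases = phases, summary = summary,
       par = compute_par_from_summary(summary))
}

#' Load and validate a recording, with a quality report
#'
#' Loads a multi-page TIFF (or accepts an existing video object),
#' checks the shape/calibration invariants and computes two quality
#' scores: the mean Sobel edge energy (are the fasciae visible?) and the
#' mean frame-to-frame correlation (is the content stable?). A video
#' scoring below the thresholds is flagged, not rejected — mirroring the
#' fact that exclusion for poor image quality is an operator decision.
#'
#' @param input TIFF path or an [ultrasound_video].
#' @param pixel_spacing calibration in mm/pixel (required for a path).
#' @param frame_rate optional Hz.
#' @param min_edge_energy,min_frame_correlation permissive flag-only
#'   thresholds.
#' @return list with `video`, `quality` (scores + `flagged` logical +
#'   `reasons`).
#' @export
validate_video <- function(input, pixel_spacing = NULL, frame_rate = NULL,
                           min_edge_energy = 1.0,
                           min_frame_correlation = 0.2) {
  video <- if (inherits(input, "ultrasound_video")) input else {
    if (is.null(pixel_spacing))
      stop("pixel_spacing is required when loading from a file")
    ultrasound_video(read_tiff_stack(input), pixel_spacing, frame_rate)
  }
  idx <- unique(round(seq(1, n_frames(video),
                          length.out = min(10L, n_frames(video)))))
  energy <- mean(vapply(idx, function(i)
    sobel_edge_energy(video$frames[[i]]), numeric(1)))
  corr <- if (n_frames(video) < 2L) 1 else {
    pairs <- utils::head(idx, -1L)
    mean(vapply(seq_along(pairs), function(j)
      tryCatch(zncc(video$frames[[idx[j]]], video$frames[[idx[j + 1L]]]),
               error = function(e) 0), numeric(1)))
  }
  reasons <- character()
  if (energy < min_edge_energy)
    reasons <- c(reasons, sprintf("low edge energy (%.3f < %.3f)",
                                  energy, min_edge_energy))
  if (corr < min_frame_correlation)
    reasons <- c(reasons, sprintf("low frame-to-frame correlation (%.3f < %.3f)",
                                  corr, min_frame_correlation))
  list(video = video,
       quality = list(edge_energy = energy, frame_correlation = corr,
                      flagged = length(reasons) > 0L, reasons = reasons))
}

#' One-command end-to-end pipeline run
#'
#' Runs simulate (optional) -> validate -> segment -> track -> measure
#' -> PAR on one recording, writes every stage output and a run manifest
#' (config echo, seed, per-stage status, file list with MD5 hashes) into
#' `out_dir`. On a stage failure the manifest records the failure point
#' and the remaining stages are skipped.
#'
#' @param input TIFF path, fixture directory (from [write_fixture()]),
#'   or `NULL` to simulate with `script`.
#' @param out_dir output directory.
#' @param pixel_spacing calibration, required for a bare TIFF input.
#' @param frame_rate optional Hz for a bare TIFF input.
#' @param script a [contraction_script] used when `input` is `NULL`.
#' @param seed RNG seed, recorded in the manifest.
#' @param viterbi,tracker,phase_params,correction,rest_mode forwarded to
#'   [measure_video()].
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(input = NULL, out_dir, pixel_spacing = NULL,
                         frame_rate = NULL, script = NULL, seed = 1L,
                         viterbi = viterbi_config(),
                         tracker = tracker_config(),
                         phase_params = list(), correction = NULL,
                         rest_mode = "pre") {
  if (is.null(input) && is.null(script))
    stop("either an input recording or a simulation script is required")
  if (!is.null(input) && is.character(input) && !file.exists(input) &&
      !dir.exists(input))
    stop("input does not exist: ", input)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  stages <- list()
  files <- character()
  note <- function(stage, status, detail = NULL)
    stages[[length(stages) + 1L]] <<- list(stage = stage, status = status,
                                           detail = detail)
  result <- NULL
  failed <- FALSE
  run_stage <- function(stage, expr) {
    if (failed) { note(stage, "skipped"); return(NULL) }
    out <- tryCatch(expr, error = function(e) {
      note(stage, "failed", conditionMessage(e)); failed <<- TRUE; NULL
    })
    if (!failed) note(stage, "ok")
    out
  }

  video <- NULL; truth <- NULL
  if (is.null(input)) {
    sim <- run_stage("simulate", {
      g <- generate_video(script, seed = seed)
      write_fixture(g$video, g$truth, file.path(out_dir, "fixture"),
                    seed = seed)
      g
    })
    if (!is.null(sim)) {
      video <- sim$video; truth <- sim$truth
      files <- c(files, file.path("fixture",
                                  c("frames.tiff", "truth.csv",
                                    "truth.json", "manifest.json")))
    }
  } else {
    loaded <- run_stage("load", {
      if (is.character(input) && dir.exists(input)) {
        fx <- load_fixture(input)
        fx$video
      } else validate_video(input, pixel_spacing, frame_rate)$video
    })
    video <- loaded
  }

  quality <- run_stage("validate", validate_video(video)$quality)
  meas <- run_stage("measure", measure_video(
    video, viterbi = viterbi, tracker = tracker, correction = correction,
    rest_mode = rest_mode, phase_params = phase_params))

  if (is.null(meas)) {
    note("write", "skipped")
  } else {
    run_stage("write", {
      write_segmentation_json(meas$segmentation,
                              file.path(out_dir, "segmentation.json"))
      write_tracks_csv(meas$tracks, file.path(out_dir, "tracks.csv"))
      write_trace_csv(meas$trace, file.path(out_dir, "trace.csv"))
      write_phases_json(meas$phases, file.path(out_dir, "phases.json"))
      par_df <- cbind(meas$summary,
                      PAR = rep(meas$par, nrow(meas$summary)))
      utils::write.csv(par_df, file.path(out_dir, "par.csv"),
                       row.names = FALSE)
      files <<- c(files, "segmentation.json", "tracks.csv", "trace.csv",
                  "phases.json", "par.csv")
    })
  }

  file_entries <- lapply(files, function(f) {
    p <- file.path(out_dir, f)
    list(path = f, md5 = unname(tools::md5sum(p)))
  })
  manifest <- list(
    package = "fasciatrack",
    version = as.character(utils::packageVersion("fasciatrack")),
    seed = seed,
    config = list(viterbi = unclass(viterbi), tracker = unclass(tracker),
                  phase_params = phase_params, rest_mode = rest_mode),
    quality = quality,
    par = if (is.null(meas)) NULL else meas$par,
    true_par = if (is.null(truth)) NULL else truth$par,
    stages = stages,
    files = file_entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (failed)
    warning("pipeline failed; see manifest stages for the failure point")
  invisible(manifest)
}
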