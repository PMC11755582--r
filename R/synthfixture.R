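MUSCLES <- c("OE", "OI", "TrA")

#' Scripted contraction for the synthetic ultrasound generator
#'
#' Describes a synthetic recording of the lateral abdominal wall: three
#' muscle layers (OE superficial, OI middle, TrA deep) bounded by four
#' bright fasciae, with a scripted rest -> ramp -> hold -> release ->
#' rest thickness profile per muscle, optional in-plane drift, and
#' speckle-noise parameters.
#'
#' Default thicknesses are the group-mean rest/contracted values of an
#' abdominal draw-in maneuver in older adults (TrA 4.61 -> 5.44 mm,
#' OI 9.34 -> 10.57 mm, OE 5.22 -> 5.40 mm), so the default script's
#' analytic preferential activation ratio is about 0.0136.
#'
#' @param n_frames number of frames (>= 1).
#' @param frame_rate acquisition rate in Hz.
#' @param rest_thickness,contracted_thickness named numeric vectors
#'   (names `OE`, `OI`, `TrA`) of thicknesses in mm, all > 0.
#' @param phase_frames integer vector
#'   `(ramp_up_start, hold_start, hold_end, release_end)`, strictly
#'   increasing, within `[1, n_frames]`: frames before `ramp_up_start`
#'   are at rest, thickness ramps linearly to the contracted value at
#'   `hold_start`, holds until `hold_end`, returns to rest at
#'   `release_end`.
#' @param drift numeric `(lateral, axial)` pixels per frame of rigid
#'   in-plane drift.
#' @param speckle_scale multiplicative speckle strength in \[0, 1)
#'   (0 = noise free).
#' @param blur_sigma Gaussian point-spread blur in pixels.
#' @param fascia_brightness peak fascia intensity (8-bit units).
#' @param fascia_width fascia band width in pixels (Gaussian
#'   cross-profile, sigma = width / 2).
#' @param fascia_amplitude,fascia_wavelength lateral sinusoidal shape of
#'   the fasciae, in pixels (amplitude 0 = flat).
#' @param rows,cols image size in pixels.
#' @param pixel_spacing calibration in mm/pixel.
#' @param top_depth_mm depth of the most superficial fascia at rest.
#' @return a validated object of class `contraction_script`.
#' @export
contraction_script <- function(
    n_frames = 100L,
    frame_rate = 30,
    rest_thickness = c(OE = 5.22, OI = 9.34, TrA = 4.61),
    contracted_thickness = c(OE = 5.40, OI = 10.57, TrA = 5.44),
    phase_frames = c(30L, 45L, 75L, 90L),
    drift = c(lateral = 0, axial = 0),
    speckle_scale = 0.3,
    blur_sigma = 1,
    fascia_brightness = 200,
    fascia_width = 3,
    fascia_amplitude = 3,
    fascia_wavelength = 150,
    rows = 256L,
    cols = 384L,
    pixel_spacing = 0.1,
    top_depth_mm = 3) {
  script <- structure(
    list(n_frames = as.integer(n_frames), frame_rate = frame_rate,
         rest_thickness = rest_thickness,
         contracted_thickness = contracted_thickness,
         phase_frames = as.integer(phase_frames), drift = drift,
         speckle_scale = speckle_scale, blur_sigma = blur_sigma,
         fascia_brightness = fascia_brightness, fascia_width = fascia_width,
         fascia_amplitude = fascia_amplitude,
         fascia_wavelength = fascia_wavelength,
         rows = as.integer(rows), cols = as.integer(cols),
         pixel_spacing = pixel_spacing, top_depth_mm = top_depth_mm),
    class = "contraction_script")
  validate_script(script)
  script
}

validate_script <- function(s) {
  fail <- function(field, why) stop("invalid ContractionScript: field '",
                                    field, "' ", why, call. = FALSE)
  if (!is.numeric(s$n_frames) || s$n_frames < 1L) fail("n_frames", "must be >= 1")
  if (s$frame_rate <= 0) fail("frame_rate", "must be > 0")
  for (fld in c("rest_thickness", "contracted_thickness")) {
    v <- s[[fld]]
    if (!all(MUSCLES %in% names(v))) fail(fld, "must name OE, OI and TrA")
    if (any(v[MUSCLES] <= 0)) fail(fld, "must be > 0 mm")
  }
  pf <- s$phase_frames
  if (length(pf) != 4L || any(diff(pf) <= 0))
    fail("phase_frames", "must be 4 strictly increasing frame indices")
  if (pf[1] < 1L || pf[4] > s$n_frames)
    fail("phase_frames", "must lie within [1, n_frames]")
  if (s$pixel_spacing <= 0) fail("pixel_spacing", "must be > 0")
  if (s$speckle_scale < 0 || s$speckle_scale >= 1)
    fail("speckle_scale", "must be in [0, 1)")
  if (s$fascia_width <= 0) fail("fascia_width", "must be > 0")
  if (s$rows < 8L || s$cols < 8L) fail("rows/cols", "image too small")
  invisible(s)
}

#' Per-frame scripted thickness (mm) for each muscle
#'
#' Piecewise-linear interpolation of the rest -> contracted -> rest
#' profile defined by `phase_frames`.
#'
#' @param script a `contraction_script`.
#' @return `n_frames` x 3 matrix with columns `OE`, `OI`, `TrA`.
#' @export
script_thickness <- function(script) {
  act <- script_activation(script)  # 0 (rest) .. 1 (contracted)
  r <- script$rest_thickness[MUSCLES]
  k <- script$contracted_thickness[MUSCLES]
  out <- outer(act, k - r) + matrix(r, script$n_frames, 3, byrow = TRUE)
  colnames(out) <- MUSCLES
  out
}

#' Per-frame phase labels implied by a script
#'
#' The continuous activation profile is binarized at 50%: a frame is
#' `contracted` when the scripted activation is at least halfway from
#' rest to the contracted plateau, `rest` otherwise. (The midpoint is
#' the natural two-label truth for a ramped contraction and matches the
#' half-rise convention used by the phase detector.)
#'
#' @param script a `contraction_script`.
#' @return character vector (`rest`, `contracted`).
#' @export
script_phase <- function(script) {
  act <- script_activation(script)
  ifelse(act >= 0.5, "contracted", "rest")
}

script_activation <- function(script) {
  pf <- script$phase_frames
  f <- seq_len(script$n_frames)
  act <- numeric(script$n_frames)
  act[f >= pf[2] & f <= pf[3]] <- 1
  ramp_up <- f > pf[1] & f < pf[2]
  act[ramp_up] <- (f[ramp_up] - pf[1]) / (pf[2] - pf[1])
  ramp_down <- f > pf[3] & f < pf[4]
  act[ramp_down] <- 1 - (f[ramp_down] - pf[3]) / (pf[4] - pf[3])
  act
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Render a synthetic B-mode-like video with known ground truth
#'
#' Renders each frame as a piecewise-constant tissue template (muscle
#' bands slightly brighter than background), adds the four fasciae as
#' bright ridges with a Gaussian cross-profile, applies multiplicative
#' exponential speckle, blurs with a small Gaussian point-spread
#' function and quantizes to 8 bit. Fully deterministic given
#' `(script, seed)`.
#'
#' @param script a `contraction_script`.
#' @param seed integer RNG seed.
#' @return list with components `video` (an [ultrasound_video]) and
#'   `truth` (class `ground_truth`: per-frame boundary matrices, true
#'   thickness matrix in mm, per-frame phase labels, and the analytic
#'   PAR of the script).
#' @export
generate_video <- function(script, seed = 1L) {
  validate_script(script)
  th <- script_thickness(script)           # mm, n_frames x 3
  nr <- script$rows; nc <- script$cols
  sp <- script$pixel_spacing
  colv <- seq_len(nc)
  sig <- script$fascia_width / 2
  tissue_levels <- c(background = 30, OE = 45, OI = 40, TrA = 50)

  frames <- vector("list", script$n_frames)
  boundaries <- vector("list", script$n_frames)
  with_seed(seed, {
    # speckle arises from tissue-attached scatterers: draw one noise
    # field in tissue coordinates and translate it with the drift, so
    # the pattern moves with the tissue instead of twinkling
    pad <- min(256L, ceiling(max(abs(script$drift)) *
                               (script$n_frames - 1)) + 4L)
    noise_field <- if (script$speckle_scale > 0)
      matrix(stats::rexp((nr + 2L * pad) * (nc + 2L * pad)),
             nr + 2L * pad, nc + 2L * pad)
    else NULL
    rowg <- matrix(seq_len(nr), nr, nc)
    colg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    for (t in seq_len(script$n_frames)) {
      lat <- script$drift[1] * (t - 1)
      axi <- script$drift[2] * (t - 1)
      shape <- if (script$fascia_amplitude > 0)
        script$fascia_amplitude *
          sin(2 * pi * (colv + lat) / script$fascia_wavelength)
      else rep(0, nc)
      b <- matrix(0, 4, nc)
      b[1, ] <- script$top_depth_mm / sp + shape + axi
      b[2, ] <- b[1, ] + th[t, "OE"] / sp
      b[3, ] <- b[2, ] + th[t, "OI"] / sp
      b[4, ] <- b[3, ] + th[t, "TrA"] / sp
      if (max(b) > nr - 4 || min(b) < 4)
        stop("scripted geometry leaves the image: increase rows or ",
             "reduce thickness/drift")
      img <- matrix(tissue_levels["background"], nr, nc)
      rowgrid <- matrix(seq_len(nr), nr, nc)
      for (m in 1:3) {
        upper <- matrix(b[m, ], nr, nc, byrow = TRUE)
        lower <- matrix(b[m + 1, ], nr, nc, byrow = TRUE)
        img[rowgrid >= upper & rowgrid < lower] <- tissue_levels[MUSCLES[m]]
      }
      for (k in 1:4) {
        lo <- max(1L, floor(min(b[k, ]) - 4 * sig))
        hi <- min(nr, ceiling(max(b[k, ]) + 4 * sig))
        sub <- lo:hi
        ridge <- script$fascia_brightness *
          exp(-(outer(sub, b[k, ], "-"))^2 / (2 * sig^2))
        img[sub, ] <- pmax(img[sub, ], ridge)
      }
      if (script$speckle_scale > 0) {
        # tissue coordinate of image pixel (r, c) at this frame
        samp <- bilinear_sample(noise_field,
                                as.vector(rowg) - axi + pad,
                                as.vector(colg) + lat + pad)
        img <- img * (1 - script$speckle_scale +
                        script$speckle_scale * matrix(samp, nr, nc))
      }
      img <- gaussian_blur(img, script$blur_sigma)
      frames[[t]] <- pmin(pmax(round(img), 0), 255)
      boundaries[[t]] <- b
    }
  })

  truth <- structure(
    list(boundaries = boundaries, thickness_mm = th,
         phase = script_phase(script),
         par = script_par(script), script = script),
    class = "ground_truth")
  list(video = ultrasound_video(frames, pixel_spacing = sp,
                                frame_rate = script$frame_rate),
       truth = truth)
}

#' Analytic PAR implied by a script's rest and contracted thicknesses
#' @param script a `contraction_script`.
#' @return dimensionless PAR value.
#' @export
script_par <- function(script) {
  r <- script$rest_thickness; k <- script$contracted_thickness
  compute_par(TrA_R = r[["TrA"]], OI_R = r[["OI"]], OE_R = r[["OE"]],
              TrA_C = k[["TrA"]], OI_C = k[["OI"]], OE_C = k[["OE"]])
}

#' Write a synthetic fixture to disk
#'
#' Writes the frame stack as a multi-page TIFF, the ground-truth
#' thickness trace as CSV (columns `frame` 0-based, `muscle`,
#' `thickness_mm`, `phase`), the script echo plus analytic PAR as JSON,
#' and a manifest listing the files and the seed.
#'
#' @param video an [ultrasound_video].
#' @param truth the matching `ground_truth`.
#' @param directory output directory (created if needed).
#' @param seed seed to record in the manifest.
#' @return path of the manifest JSON, invisibly.
#' @export
write_fixture <- function(video, truth, directory, seed = NA_integer_) {
  if (!dir.exists(directory))
    if (!dir.create(directory, recursive = TRUE))
      stop("cannot create directory: ", directory)
  tiff_path <- file.path(directory, "frames.tiff")
  csv_path <- file.path(directory, "truth.csv")
  json_path <- file.path(directory, "truth.json")
  manifest_path <- file.path(directory, "manifest.json")

  write_tiff_stack(video, tiff_path)
  nf <- nrow(truth$thickness_mm)
  df <- data.frame(
    frame = rep(seq_len(nf) - 1L, times = 3L),
    muscle = rep(MUSCLES, each = nf),
    thickness_mm = as.vector(truth$thickness_mm),
    phase = rep(truth$phase, times = 3L))
  utils::write.csv(df, csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(par = truth$par, phase = truth$phase,
         script = unclass(truth$script)),
    json_path, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(seed = seed,
         pixel_spacing = video$pixel_spacing,
         frame_rate = video$frame_rate,
         n_frames = n_frames(video),
         files = basename(c(tiff_path, csv_path, json_path))),
    manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest_path)
}

#' Load a fixture directory written by [write_fixture()]
#' @param directory fixture directory.
#' @return list with `video`, `truth_table` (data.frame) and `manifest`.
#' @export
load_fixture <- function(directory) {
  manifest <- jsonlite::read_json(file.path(directory, "manifest.json"),
                                  simplifyVector = TRUE)
  frames <- read_tiff_stack(file.path(directory, "frames.tiff"))
  video <- ultrasound_video(frames, pixel_spacing = manifest$pixel_spacing,
                            frame_rate = manifest$frame_rate)
  truth_table <- utils::read.csv(file.path(directory, "truth.csv"))
  list(video = video, truth_table = truth_table, manifest = manifest)
}
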