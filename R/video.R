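#' Calibrated B-mode ultrasound frame stack
#'
#' The central video container: a list of equally sized grayscale frames
#' (numeric matrices, row index = axial depth increasing downward,
#' column index = lateral position) plus the physical calibration.
#'
#' @param frames list of numeric matrices, all of identical dimensions,
#'   or a 3-D array indexed `[frame, row, col]`.
#' @param pixel_spacing physical size of one pixel in mm/pixel (> 0).
#' @param frame_rate acquisition rate in Hz, or `NULL` if unknown.
#' @return an object of class `ultrasound_video` with fields `frames`,
#'   `pixel_spacing`, `frame_rate`.
#' @export
#' @examples
#' v <- ultrasound_video(list(matrix(0, 8, 8)), pixel_spacing = 0.1)
#' n_frames(v)
ultrasound_video <- function(frames, pixel_spacing, frame_rate = NULL) {
  if (is.array(frames) && length(dim(frames)) == 3L) {
    frames <- lapply(seq_len(dim(frames)[1]), function(i) frames[i, , ])
  }
  if (!is.list(frames) || length(frames) < 1L)
    stop("frames must be a non-empty list of matrices (n_frames >= 1)")
  if (!all(vapply(frames, is.matrix, logical(1))))
    stop("every frame must be a matrix")
  d <- dim(frames[[1]])
  same <- vapply(frames, function(f) identical(dim(f), d), logical(1))
  if (!all(same))
    stop("all frames must share the same shape; frame ",
         which(!same)[1], " differs")
  if (!is.numeric(pixel_spacing) || length(pixel_spacing) != 1L ||
      is.na(pixel_spacing) || pixel_spacing <= 0)
    stop("pixel_spacing must be a single value > 0 (mm/pixel)")
  if (!is.null(frame_rate) && (!is.numeric(frame_rate) || frame_rate <= 0))
    stop("frame_rate must be > 0 (Hz) or NULL")
  structure(
    list(frames = frames, pixel_spacing = pixel_spacing,
         frame_rate = frame_rate),
    class = "ultrasound_video")
}

#' @rdname ultrasound_video
#' @param video an `ultrasound_video`.
#' @export
n_frames <- function(video) length(video$frames)

#' @rdname ultrasound_video
#' @export
frame_dim <- function(video) dim(video$frames[[1]])

#' @export
print.ultrasound_video <- function(x, ...) {
  d <- frame_dim(x)
  cat(sprintf(
    "ultrasound_video: %d frame(s) of %d x %d px, %.4g mm/px%s\n",
    n_frames(x), d[1], d[2], x$pixel_spacing,
    if (is.null(x$frame_rate)) "" else sprintf(", %.4g Hz", x$frame_rate)))
  invisible(x)
}
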