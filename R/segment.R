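#' Configuration of the brightest-path fascia extraction
#'
#' @param max_vertical_step largest allowed row change per column
#'   transition (pixels, >= 1).
#' @param step_penalty brightness units subtracted per pixel of vertical
#'   step (>= 0); discourages jagged paths through speckle maxima.
#' @param exclusion_halfwidth half-width in pixels of the band masked
#'   around an accepted path before the next path is extracted; also
#'   guarantees extracted paths cannot cross.
#' @param presmooth_sigma Gaussian pre-smoothing (pixels) applied before
#'   the dynamic program, to suppress isolated speckle maxima.
#' @return object of class `viterbi_config`.
#' @export
viterbi_config <- function(max_vertical_step = 2L, step_penalty = 2.0,
                           exclusion_halfwidth = 6L, presmooth_sigma = 1) {
  if (max_vertical_step < 1L) stop("max_vertical_step must be >= 1")
  if (step_penalty < 0 || presmooth_sigma < 0)
    stop("penalties and smoothing must be >= 0")
  if (exclusion_halfwidth < 1L) stop("exclusion_halfwidth must be >= 1")
  structure(list(max_vertical_step = as.integer(max_vertical_step),
                 step_penalty = step_penalty,
                 exclusion_halfwidth = as.integer(exclusion_halfwidth),
                 presmooth_sigma = presmooth_sigma),
            class = "viterbi_config")
}

#' Per-frame fascia segmentation
#'
#' Four ordered boundary polylines (row coordinate per column), boundary
#' 1 = superficial border of OE, 2 = OE/OI interface, 3 = OI/TrA
#' interface, 4 = deep border of TrA. Rows must strictly increase with
#' boundary index in every column.
#'
#' @param frame_index 1-based frame index the segmentation belongs to.
#' @param boundaries 4 x width numeric matrix of row coordinates.
#' @param img_dim `c(rows, cols)` of the source frame.
#' @param col_start first image column (1-based) covered by the
#'   segmentation.
#' @param source one of `automatic`, `corrected`, `propagated`.
#' @return object of class `fascia_segmentation`.
#' @export
fascia_segmentation <- function(frame_index, boundaries, img_dim,
                                col_start = 1L,
                                source = c("automatic", "corrected",
                                           "propagated")) {
  source <- match.arg(source)
  if (!is.matrix(boundaries) || nrow(boundaries) != 4L)
    stop("boundaries must be a 4 x width matrix")
  seg <- structure(
    list(frame_index = as.integer(frame_index), boundaries = boundaries,
         img_dim = as.integer(img_dim), col_start = as.integer(col_start),
         source = source),
    class = "fascia_segmentation")
  validate_segmentation(seg)
  seg
}

validate_segmentation <- function(seg) {
  b <- seg$boundaries
  bad_order <- which(apply(b, 2, function(col) any(diff(col) <= 0)))
  if (length(bad_order))
    stop("boundaries must strictly increase top -> bottom in every ",
         "column; violated at column(s) ",
         paste(utils::head(bad_order + seg$col_start - 1L, 10L),
               collapse = ", "))
  if (min(b) < 1 || max(b) > seg$img_dim[1])
    stop("boundary rows outside image bounds")
  if (seg$col_start < 1L ||
      seg$col_start + ncol(b) - 1L > seg$img_dim[2])
    stop("column range outside image bounds")
  invisible(seg)
}

#' Select the initial frame for segmentation
#'
#' Returns the frame with the highest mean Sobel gradient magnitude,
#' i.e. the frame on which the fascia interfaces are sharpest. Ties are
#' broken by the lowest frame index.
#'
#' @param video an [ultrasound_video].
#' @return 1-based frame index.
#' @export
select_initial_frame <- function(video) {
  if (!inherits(video, "ultrasound_video")) stop("not an ultrasound_video")
  energies <- vapply(video$frames, sobel_edge_energy, numeric(1))
  which.max(energies)  # first maximum = lowest index
}

#' Brightest path through an image by dynamic programming
#'
#' Finds the left-to-right path (one row per column, vertical step at
#' most `max_vertical_step` pixels) maximizing the summed brightness
#' minus `step_penalty` x |row step|, by a Viterbi-style dynamic program
#' with backtracking. Ties prefer the smallest row.
#'
#' @param image numeric matrix; masked pixels may be `-Inf` (or very
#'   negative) and are avoided.
#' @param row_band `c(first, last)` rows to which the path is
#'   restricted.
#' @param config a [viterbi_config] (pre-smoothing is NOT applied here).
#' @return list with `rows` (integer row per column, in image
#'   coordinates) and `score` (the optimal path score).
#' @export
brightest_path <- function(image, row_band = c(1L, nrow(image)),
                           config = viterbi_config()) {
  if (!is.matrix(image)) stop("image must be a matrix")
  row_band <- as.integer(row_band)
  if (row_band[1] > row_band[2] || row_band[1] < 1L ||
      row_band[2] > nrow(image))
    stop("row_band empty or outside image")
  band <- image[row_band[1]:row_band[2], , drop = FALSE]
  nr <- nrow(band); nc <- ncol(band)
  s <- min(config$max_vertical_step, nr - 1L)
  pen <- config$step_penalty

  score <- band[, 1]
  ptr <- matrix(0L, nr, nc)
  if (nc > 1L) {
    for (j in 2:nc) {
      best <- rep(-Inf, nr)
      arg <- integer(nr)
      for (d in seq.int(-s, s)) {
        # predecessor row p = r + d; iterate d ascending so that ties
        # keep the smallest predecessor row
        p <- seq_len(nr) + d
        ok <- p >= 1L & p <= nr
        cand <- rep(-Inf, nr)
        cand[ok] <- score[p[ok]] - pen * abs(d)
        upd <- cand > best
        best[upd] <- cand[upd]
        arg[upd] <- p[upd]
      }
      score <- band[, j] + best
      ptr[, j] <- arg
    }
  }
  final <- which.max(score)  # ties: smallest row
  if (!is.finite(score[final])) stop("no admissible path in row_band")
  rows <- integer(nc)
  rows[nc] <- final
  if (nc > 1L) for (j in nc:2) rows[j - 1L] <- ptr[rows[j], j]
  list(rows = rows + row_band[1] - 1L, score = score[final])
}

#' Extract the four fascia boundaries from one frame
#'
#' Runs the brightest-path dynamic program four times, masking an
#' exclusion band of `exclusion_halfwidth` pixels around each accepted
#' path so the next path cannot touch or cross it, then reorders the
#' four paths top -> bottom.
#'
#' @param frame 2-D numeric matrix.
#' @param config a [viterbi_config]; `presmooth_sigma` is applied once
#'   before extraction.
#' @param frame_index frame index recorded in the result.
#' @param n_paths number of fasciae to extract (4 for the OE/OI/TrA
#'   stack).
#' @return a [fascia_segmentation] with source `automatic`.
#' @export
segment_fasciae <- function(frame, config = viterbi_config(),
                            frame_index = 1L, n_paths = 4L) {
  if (!is.matrix(frame)) stop("frame must be a matrix")
  nr <- nrow(frame); nc <- ncol(frame)
  if (nr < n_paths * (2L * config$exclusion_halfwidth + 1L))
    stop("image too short to place ", n_paths, " non-crossing paths ",
         "with exclusion halfwidth ", config$exclusion_halfwidth)
  work <- gaussian_blur(frame, config$presmooth_sigma)
  h <- config$exclusion_halfwidth
  paths <- matrix(0L, n_paths, nc)
  for (i in seq_len(n_paths)) {
    bp <- tryCatch(brightest_path(work, c(1L, nr), config),
                   error = function(e)
                     stop("cannot place ", n_paths, " non-crossing paths: ",
                          conditionMessage(e), call. = FALSE))
    paths[i, ] <- bp$rows
    for (j in seq_len(nc)) {
      lo <- max(1L, bp$rows[j] - h); hi <- min(nr, bp$rows[j] + h)
      work[lo:hi, j] <- -Inf
    }
  }
  paths <- paths[order(rowMeans(paths)), , drop = FALSE]
  paths <- enforce_boundary_order(paths, nr)
  fascia_segmentation(frame_index, paths, img_dim = c(nr, nc),
                      source = "automatic")
}

# Order-preserving projection: per column, sort the four rows (pmin/
# pmax sorting network, vectorized over columns) and impose a minimal
# separation of 1 px, clamped to the image.
enforce_boundary_order <- function(b, n_rows, min_sep = 1) {
  stopifnot(nrow(b) == 4L)
  a <- pmin(b[1, ], b[2, ]); bb <- pmax(b[1, ], b[2, ])
  c2 <- pmin(b[3, ], b[4, ]); d <- pmax(b[3, ], b[4, ])
  lo <- pmin(a, c2); hi <- pmax(bb, d)
  m1 <- pmax(a, c2); m2 <- pmin(bb, d)
  mid_lo <- pmin(m1, m2); mid_hi <- pmax(m1, m2)
  r1 <- lo
  r2 <- pmax(mid_lo, r1 + min_sep)
  r3 <- pmax(mid_hi, r2 + min_sep)
  r4 <- pmax(hi, r3 + min_sep)
  over <- pmax(r4 - n_rows, 0)
  r1 <- pmax(r1 - over, 1)
  r2 <- pmax(r2 - over, r1 + min_sep)
  r3 <- pmax(r3 - over, r2 + min_sep)
  r4 <- pmax(r4 - over, r3 + min_sep)
  rbind(r1, r2, r3, r4, deparse.level = 0)
}

#' Apply operator-supplied boundary corrections
#'
#' Replaces one or more boundary polylines of an automatic segmentation
#' with manually corrected ones (the operator's review step). The
#' corrected segmentation is re-validated: a correction that breaks the
#' top -> bottom ordering is rejected with the offending columns named.
#'
#' @param segmentation a [fascia_segmentation].
#' @param correction either a path to a correction JSON file (fields
#'   `boundaries`: object mapping 0-based boundary index to an array of
#'   row values, 0-based) or a list of elements
#'   `list(boundary = <1..4>, rows = <numeric>)`.
#' @return corrected [fascia_segmentation] with source `corrected`; the
#'   input unchanged (still `automatic`) if the correction is empty.
#' @export
apply_correction <- function(segmentation, correction) {
  if (is.character(correction) && length(correction) == 1L) {
    correction <- read_correction_json(correction)
  }
  if (length(correction) == 0L) return(segmentation)
  b <- segmentation$boundaries
  for (corr in correction) {
    idx <- corr$boundary
    if (is.null(idx) || idx < 1L || idx > 4L)
      stop("correction boundary index must be in 1..4")
    rows <- as.numeric(corr$rows)
    if (length(rows) != ncol(b))
      stop("correction for boundary ", idx, " has ", length(rows),
           " columns; segmentation has ", ncol(b))
    b[idx, ] <- rows
  }
  bad <- which(apply(b, 2, function(col) any(diff(col) <= 0)))
  if (length(bad))
    stop("correction breaks boundary ordering at column(s) ",
         paste(utils::head(bad + segmentation$col_start - 1L, 10L),
               collapse = ", "))
  fascia_segmentation(segmentation$frame_index, b, segmentation$img_dim,
                      segmentation$col_start, source = "corrected")
}

read_correction_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$boundaries) || length(j$boundaries) == 0L) return(list())
  lapply(names(j$boundaries), function(k)
    list(boundary = as.integer(k) + 1L,           # 0-based on disk
         rows = as.numeric(j$boundaries[[k]]) + 1))
}

#' Serialize / read a segmentation as JSON (0-based on disk)
#'
#' The on-disk format uses 0-based frame and row/column coordinates and
#' a half-open `column_range`; the R objects are 1-based.
#'
#' @param segmentation a [fascia_segmentation].
#' @param path JSON file path.
#' @return `write_segmentation_json`: `path`, invisibly;
#'   `read_segmentation_json`: a [fascia_segmentation].
#' @export
write_segmentation_json <- function(segmentation, path) {
  b <- segmentation$boundaries
  jsonlite::write_json(
    list(frame_index = segmentation$frame_index - 1L,
         column_range = c(segmentation$col_start - 1L,
                          segmentation$col_start - 1L + ncol(b)),
         img_dim = segmentation$img_dim,
         boundaries = lapply(seq_len(4), function(i) b[i, ] - 1),
         source = segmentation$source),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_segmentation_json
#' @export
read_segmentation_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  b <- if (is.matrix(j$boundaries)) j$boundaries + 1 else
    do.call(rbind, lapply(j$boundaries, as.numeric)) + 1
  fascia_segmentation(j$frame_index + 1L, b, img_dim = j$img_dim,
                      col_start = j$column_range[1] + 1L,
                      source = j$source)
}
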