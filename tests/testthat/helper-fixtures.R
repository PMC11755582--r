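# Shared fixtures and independent oracles for the test suite.

# A coarse, fast script: 0.2 mm/px halves the pixel size of the muscle
# stack so whole videos stay small. Same physiology as the defaults.
small_script <- function(...) {
  args <- list(n_frames = 40L, phase_frames = c(10L, 16L, 28L, 34L),
               rows = 160L, cols = 160L, pixel_spacing = 0.2,
               fascia_wavelength = 80)
  do.call(contraction_script, utils::modifyList(args, list(...)))
}

# Independent brute-force 2-D convolution with replicate padding
# (nested loops; deliberately naive).
oracle_conv2 <- function(img, kernel) {
  nr <- nrow(img); nc <- ncol(img)
  kr <- nrow(kernel); kc <- ncol(kernel)
  pr <- (kr - 1) / 2; pc <- (kc - 1) / 2
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (a in seq_len(kr)) for (b in seq_len(kc)) {
      ii <- min(max(i + pr - (a - 1), 1), nr)
      jj <- min(max(j + pc - (b - 1), 1), nc)
      acc <- acc + kernel[a, b] * img[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

# All admissible left-to-right paths (one row per column, |step| bounded)
enumerate_paths <- function(nr, nc, step) {
  paths <- matrix(seq_len(nr), ncol = 1)
  for (j in seq_len(nc - 1)) {
    pieces <- lapply(seq.int(-step, step), function(d) {
      nxt <- paths[, ncol(paths)] + d
      keep <- nxt >= 1 & nxt <= nr
      cbind(paths[keep, , drop = FALSE], nxt[keep])
    })
    paths <- do.call(rbind, pieces)
  }
  paths
}

# Exhaustive-enumeration optimum of the penalized brightest-path
# objective; the independent oracle for the Viterbi dynamic program.
brute_best_path <- function(img, step, penalty, paths = NULL) {
  nr <- nrow(img); nc <- ncol(img)
  if (is.null(paths)) paths <- enumerate_paths(nr, nc, step)
  idx <- paths + matrix((seq_len(nc) - 1) * nr, nrow(paths), nc,
                        byrow = TRUE)
  bright <- rowSums(matrix(img[idx], nrow(paths)))
  steps <- rowSums(abs(paths[, -1, drop = FALSE] -
                         paths[, -nc, drop = FALSE]))
  scores <- bright - penalty * steps
  best <- which.max(scores)
  list(score = scores[best], rows = paths[best, ])
}

# A repeated-frame (zero motion) video built from one rendered frame
static_video <- function(seed = 1L, n = 10L) {
  g <- generate_video(small_script(), seed = seed)
  f <- g$video$frames[[5]]
  ultrasound_video(rep(list(f), n), pixel_spacing = 0.2, frame_rate = 30)
}

# Hand-built thickness trace: three points per muscle, given per-frame
# per-muscle values
make_trace <- function(values_by_muscle, frame_rate = 30) {
  nf <- length(values_by_muscle[[1]])
  out <- do.call(rbind, lapply(names(values_by_muscle), function(m)
    do.call(rbind, lapply(0:2, function(pid)
      data.frame(frame = seq_len(nf), time_s = (seq_len(nf) - 1) / frame_rate,
                 muscle = m, point_id = pid,
                 thickness_mm = values_by_muscle[[m]], flag = "ok")))))
  class(out) <- c("thickness_trace", "data.frame")
  out
}
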