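#' 2-D convolution with replicate border padding
#'
#' Small-kernel convolution used by the Sobel and Gaussian filters. The
#' border is padded by replicating edge pixels so that filter energy is
#' conserved near the frame edge (important for the initial-frame
#' selection rule, which compares whole-frame means).
#'
#' @param img numeric matrix.
#' @param kernel numeric matrix with odd dimensions.
#' @return numeric matrix of the same size as `img`.
#' @keywords internal
convolve2 <- function(img, kernel) {
  stopifnot(is.matrix(img), is.matrix(kernel))
  kr <- nrow(kernel); kc <- ncol(kernel)
  if (kr %% 2L == 0L || kc %% 2L == 0L)
    stop("kernel dimensions must be odd")
  if (nrow(img) < 1L || ncol(img) < 1L) stop("empty image")
  pr <- (kr - 1L) %/% 2L
  pc <- (kc - 1L) %/% 2L
  padded <- pad_replicate(img, pr, pc)
  out <- matrix(0, nrow(img), ncol(img))
  # convolution proper: kernel is flipped relative to cross-correlation
  for (i in seq_len(kr)) {
    for (j in seq_len(kc)) {
      w <- kernel[kr - i + 1L, kc - j + 1L]
      if (w == 0) next
      out <- out + w * padded[i:(i + nrow(img) - 1L), j:(j + ncol(img) - 1L)]
    }
  }
  out
}

pad_replicate <- function(img, pr, pc) {
  ri <- c(rep(1L, pr), seq_len(nrow(img)), rep(nrow(img), pr))
  ci <- c(rep(1L, pc), seq_len(ncol(img)), rep(ncol(img), pc))
  img[ri, ci, drop = FALSE]
}

#' Gaussian kernel and blur
#'
#' @param sigma standard deviation in pixels; `sigma = 0` is the identity.
#' @param img numeric matrix.
#' @return `gaussian_kernel`: a normalized 1-D kernel vector;
#'   `gaussian_blur`: the filtered matrix (separable filtering).
#' @keywords internal
gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  radius <- max(1L, ceiling(3 * sigma))
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' @rdname gaussian_kernel
#' @keywords internal
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gaussian_kernel(sigma)
  img <- convolve2(img, matrix(k, ncol = 1))
  convolve2(img, matrix(k, nrow = 1))
}

sobel_kernels <- function() {
  # standard 3x3 pair; gx responds to horizontal (column-wise) gradients
  gx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gy <- t(gx)
  list(gx = gx, gy = gy)
}

#' Sobel gradient magnitude and edge energy
#'
#' `sobel_magnitude` returns the per-pixel gradient magnitude using the
#' standard 3x3 Sobel pair; `sobel_edge_energy` reduces it to the frame
#' mean, the score used to pick the initial frame of a recording (the
#' frame on which the fascia interfaces are sharpest).
#'
#' @param frame 2-D numeric matrix, at least 3x3.
#' @return a matrix (`sobel_magnitude`) or a non-negative scalar
#'   (`sobel_edge_energy`).
#' @export
#' @examples
#' f <- matrix(0, 8, 8); f[4:8, ] <- 10
#' sobel_edge_energy(f) > 0
sobel_edge_energy <- function(frame) {
  mean(sobel_magnitude(frame))
}

#' @rdname sobel_edge_energy
#' @export
sobel_magnitude <- function(frame) {
  if (!is.matrix(frame)) stop("frame must be a matrix")
  if (nrow(frame) < 3L || ncol(frame) < 3L)
    stop("frame smaller than 3x3")
  k <- sobel_kernels()
  sqrt(convolve2(frame, k$gx)^2 + convolve2(frame, k$gy)^2)
}

#' Bilinear interpolation of image values
#'
#' Samples `img` at fractional (row, col) positions. Positions outside
#' the image are clamped to the border.
#'
#' @param img numeric matrix.
#' @param rows,cols numeric vectors of equal length, 1-based fractional
#'   coordinates.
#' @return numeric vector of sampled values.
#' @keywords internal
bilinear_sample <- function(img, rows, cols) {
  nr <- nrow(img); nc <- ncol(img)
  rows <- pmin.int(pmax.int(rows, 1), nr)
  cols <- pmin.int(pmax.int(cols, 1), nc)
  r0 <- pmin.int(floor(rows), nr - 1L)
  c0 <- pmin.int(floor(cols), nc - 1L)
  fr <- rows - r0
  fc <- cols - c0
  idx <- (c0 - 1) * nr + r0  # linear index of (r0, c0)
  i00 <- img[idx]
  i10 <- img[idx + 1]
  i01 <- img[idx + nr]
  i11 <- img[idx + nr + 1]
  w <- fr * fc
  i00 * (1 - fr - fc + w) + i10 * (fr - w) + i01 * (fc - w) + i11 * w
}

#' Zero-normalized cross-correlation of two equally sized regions
#' @keywords internal
zncc <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined for zero-variance region")
  stats::cor(a, b)
}

#' Downsample an image by a factor of two (blur + decimate)
#' @keywords internal
pyr_down <- function(img) {
  img <- gaussian_blur(img, 1)
  img[seq(1L, nrow(img), by = 2L), seq(1L, ncol(img), by = 2L), drop = FALSE]
}

#' Linear interpolation along a polyline stored as row-per-column
#'
#' @param rows numeric vector, row coordinate per integer column.
#' @param x fractional column positions (1-based, relative to the first
#'   element of `rows`).
#' @keywords internal
polyline_interp <- function(rows, x) {
  n <- length(rows)
  if (n == 1L) return(rep(rows, length(x)))
  stats::approx(seq_len(n), rows, xout = pmin(pmax(x, 1), n), rule = 2)$y
}
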