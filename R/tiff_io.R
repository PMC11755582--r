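# Minimal baseline TIFF support for 8-bit grayscale frame stacks.
# Written by hand because the runtime has no TIFF-capable R package.
# Writer: little-endian, uncompressed, one strip per page.
# Reader: either byte order, uncompressed 8-bit grayscale, any number of
# strips per page (covers files produced by common scientific writers).

TIFF_TYPE_BYTES <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L)

#' Write a stack of grayscale frames as a multi-page TIFF
#'
#' Frames are clamped to \[0, 255\] and rounded to 8-bit. The file is
#' uncompressed baseline TIFF, one page per frame, readable by any
#' scientific TIFF reader.
#'
#' @param frames list of numeric matrices (identical dimensions) or an
#'   `ultrasound_video`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(frames, path) {
  if (inherits(frames, "ultrasound_video")) frames <- frames$frames
  stopifnot(is.list(frames), length(frames) >= 1L)
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  n <- length(frames)
  page_bytes <- w * h
  ifd_entries <- 9L
  ifd_size <- 2L + ifd_entries * 12L + 4L
  ifd_start <- 8L + n * page_bytes

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifd_start), con, size = 4, endian = "little")
  for (f in frames) {
    if (!identical(dim(f), c(h, w)))
      stop("all frames must share the same shape")
    px <- pmin(pmax(round(f), 0), 255)
    writeBin(as.raw(as.vector(t(px))), con)  # strips are row-major
  }
  for (i in seq_len(n)) {
    data_off <- 8L + (i - 1L) * page_bytes
    next_ifd <- if (i < n) ifd_start + i * ifd_size else 0L
    writeBin(ifd_entries, con, size = 2, endian = "little")
    entries <- list(
      .tiff_entry(256L, 3L, 1L, w),           # ImageWidth
      .tiff_entry(257L, 3L, 1L, h),           # ImageLength
      .tiff_entry(258L, 3L, 1L, 8L),          # BitsPerSample
      .tiff_entry(259L, 3L, 1L, 1L),          # Compression: none
      .tiff_entry(262L, 3L, 1L, 1L),          # Photometric: BlackIsZero
      .tiff_entry(273L, 4L, 1L, data_off),    # StripOffsets
      .tiff_entry(277L, 3L, 1L, 1L),          # SamplesPerPixel
      .tiff_entry(278L, 4L, 1L, h),           # RowsPerStrip
      .tiff_entry(279L, 4L, 1L, page_bytes))  # StripByteCounts
    for (e in entries) writeBin(e, con)
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
  }
  invisible(path)
}

.tiff_entry <- function(tag, type, count, value) {
  # returns raw(12); value must fit inline (all our values do)
  out <- raw(12)
  out[1:2] <- writeBin(as.integer(tag), raw(), size = 2, endian = "little")
  out[3:4] <- writeBin(as.integer(type), raw(), size = 2, endian = "little")
  out[5:8] <- writeBin(as.integer(count), raw(), size = 4, endian = "little")
  if (type == 3L) {
    out[9:10] <- writeBin(as.integer(value), raw(), size = 2, endian = "little")
  } else {
    out[9:12] <- writeBin(as.integer(value), raw(), size = 4, endian = "little")
  }
  out
}

#' Read a multi-page grayscale TIFF as a list of matrices
#'
#' Supports uncompressed 8-bit grayscale baseline TIFF in either byte
#' order, with one or more strips per page.
#'
#' @param path TIFF file path.
#' @return list of numeric matrices with values in \[0, 255\].
#' @export
read_tiff_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw_all) < 8L) stop("not a TIFF file (too short): ", path)
  order_tag <- rawToChar(raw_all[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big"
    else stop("not a TIFF file: ", path)
  rd_int <- function(off, size, n = 1L) {
    readBin(raw_all[(off + 1L):(off + size * n)], "integer", n = n,
            size = size, endian = endian, signed = size >= 4L)
  }
  if (rd_int(2L, 2L) != 42L) stop("not a TIFF file: ", path)
  ifd_off <- rd_int(4L, 4L)
  frames <- list()
  while (ifd_off != 0L) {
    n_entry <- rd_int(ifd_off, 2L)
    tags <- list()
    for (k in seq_len(n_entry)) {
      e_off <- ifd_off + 2L + (k - 1L) * 12L
      tag <- rd_int(e_off, 2L)
      type <- rd_int(e_off + 2L, 2L)
      count <- rd_int(e_off + 4L, 4L)
      tb <- TIFF_TYPE_BYTES[as.character(type)]
      if (is.na(tb)) { tags[[as.character(tag)]] <- NULL; next }
      total <- tb * count
      val_off <- if (total <= 4L) e_off + 8L else rd_int(e_off + 8L, 4L)
      vals <- if (type %in% c(3L, 4L)) rd_int(val_off, tb, count) else
        as.integer(raw_all[(val_off + 1L):(val_off + total)])
      tags[[as.character(tag)]] <- vals
    }
    w <- tags[["256"]][1]; h <- tags[["257"]][1]
    comp <- if (is.null(tags[["259"]])) 1L else tags[["259"]][1]
    bps <- if (is.null(tags[["258"]])) 1L else tags[["258"]][1]
    spp <- if (is.null(tags[["277"]])) 1L else tags[["277"]][1]
    if (comp != 1L) stop("unsupported TIFF compression: ", comp)
    if (bps != 8L || spp != 1L)
      stop("only 8-bit single-sample grayscale TIFF is supported")
    offs <- tags[["273"]]; counts <- tags[["279"]]
    bytes <- unlist(lapply(seq_along(offs), function(i)
      as.integer(raw_all[(offs[i] + 1L):(offs[i] + counts[i])])))
    if (length(bytes) != w * h) stop("corrupt TIFF page (byte count mismatch)")
    frames[[length(frames) + 1L]] <- matrix(as.numeric(bytes), nrow = h,
                                            ncol = w, byrow = TRUE)
    ifd_off <- rd_int(ifd_off + 2L + n_entry * 12L, 4L)
  }
  if (length(frames) == 0L) stop("TIFF contains no pages: ", path)
  frames
}
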