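#' Tracker configuration
#'
#' Parameters of the point tracker and of the flow post-filter used for
#' segmentation propagation. `sigma` is the tracker's Gaussian
#' pre-smoothing scale expressed as a fraction of the tracking window
#' (so the default 0.04 with a 21 px window smooths with sigma of about
#' 0.84 px). `fgs_lambda` and `fgs_sigma` parameterize the
#' fast-global-smoother post-filter applied to the displacement field
#' along each boundary: `fgs_lambda` is the regularization strength and
#' `fgs_sigma` the edge sensitivity (intensity units) that lets the
#' smoothing relax across brightness edges.
#'
#' @param sigma pre-smoothing scale, fraction of `window`.
#' @param fgs_lambda flow post-filter regularization (> 0).
#' @param fgs_sigma flow post-filter edge sensitivity (> 0).
#' @param window Lucas-Kanade window size in pixels (odd).
#' @param levels pyramid levels (>= 1).
#' @param max_iter,epsilon iteration control of the LK solver.
#' @param keyframes integer vector of segmented (key) frame indices.
#' @return object of class `tracker_config`.
#' @export
tracker_config <- function(sigma = 0.04, fgs_lambda = 5000, fgs_sigma = 3,
                           window = 21L, levels = 3L, max_iter = 12L,
                           epsilon = 0.01, keyframes = integer()) {
  if (sigma <= 0 || fgs_lambda <= 0 || fgs_sigma <= 0)
    stop("sigma, fgs_lambda and fgs_sigma must all be > 0")
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  if (levels < 1L) stop("levels must be >= 1")
  structure(list(sigma = sigma, fgs_lambda = fgs_lambda,
                 fgs_sigma = fgs_sigma, window = as.integer(window),
                 levels = as.integer(levels), max_iter = as.integer(max_iter),
                 epsilon = epsilon, keyframes = as.integer(keyframes)),
            class = "tracker_config")
}

#' Build a Gaussian image pyramid for tracking
#' @param img numeric matrix.
#' @param levels number of levels.
#' @param presmooth_sigma Gaussian smoothing (pixels) applied at the
#'   finest level before downsampling.
#' @keywords internal
build_pyramid <- function(img, levels, presmooth_sigma = 0) {
  if (presmooth_sigma > 0) img <- gaussian_blur(img, presmooth_sigma)
  pyr <- vector("list", levels)
  pyr[[1]] <- img
  for (l in seq_len(levels - 1L)) {
    prev <- pyr[[l]]
    if (min(dim(prev)) < 16L) { pyr <- pyr[seq_len(l)]; break }
    pyr[[l + 1L]] <- pyr_down(prev)
  }
  pyr
}

# Batched pyramidal Lucas-Kanade: track all points from `ref_pyr` to
# `cur_pyr` simultaneously. pts is an n x 2 matrix of (row, col) in the
# reference frame. `init_d` is an optional n x 2 initial displacement
# (e.g. the previous frame's solution); with a warm start only the
# finest pyramid level is iterated. Returns n x 2 tracked positions
# plus a logical `ok`.
lk_track <- function(ref_pyr, cur_pyr, pts, config, init_d = NULL) {
  n <- nrow(pts)
  levels <- if (is.null(init_d)) min(length(ref_pyr), length(cur_pyr)) else 1L
  hw <- (config$window - 1L) %/% 2L
  off <- expand.grid(dr = -hw:hw, dc = -hw:hw)
  m <- nrow(off)  # window pixels per point
  odr <- rep(off$dr, times = n)
  odc <- rep(off$dc, times = n)

  d <- if (is.null(init_d)) matrix(0, n, 2) else init_d
  ok <- rep(TRUE, n)
  for (l in levels:1) {
    scale <- 2^(l - 1L)
    ref <- ref_pyr[[l]]; cur <- cur_pyr[[l]]
    pr <- rep(pts[, 1] / scale, each = m) + odr
    pc <- rep(pts[, 2] / scale, each = m) + odc
    # template and its gradients, fixed per level
    refW <- bilinear_sample(ref, pr, pc)
    Ix <- (bilinear_sample(ref, pr, pc + 1) -
             bilinear_sample(ref, pr, pc - 1)) / 2
    Iy <- (bilinear_sample(ref, pr + 1, pc) -
             bilinear_sample(ref, pr - 1, pc)) / 2
    dim(refW) <- dim(Ix) <- dim(Iy) <- c(m, n)
    gxx <- colSums(Ix * Ix); gxy <- colSums(Ix * Iy); gyy <- colSums(Iy * Iy)
    det <- gxx * gyy - gxy^2
    solvable <- ok & det > 1e-6
    dl <- d / scale
    for (it in seq_len(config$max_iter)) {
      act <- which(solvable)
      if (!length(act)) break
      ai <- rep((act - 1L) * m, each = m) + seq_len(m)
      curW <- bilinear_sample(cur,
                              pr[ai] + rep(dl[act, 1], each = m),
                              pc[ai] + rep(dl[act, 2], each = m))
      e <- refW[, act, drop = FALSE] - matrix(curW, m)
      bx <- colSums(Ix[, act, drop = FALSE] * e)
      by <- colSums(Iy[, act, drop = FALSE] * e)
      # solve 2x2 [gxx gxy; gxy gyy] delta = [bx; by]
      dx <- (gyy[act] * bx - gxy[act] * by) / det[act]
      dy <- (gxx[act] * by - gxy[act] * bx) / det[act]
      dl[act, 1] <- dl[act, 1] + dy
      dl[act, 2] <- dl[act, 2] + dx
      conv <- abs(dx) < config$epsilon & abs(dy) < config$epsilon
      solvable[act[conv]] <- FALSE
      diverged <- abs(dl[act, 1]) > nrow(ref) | abs(dl[act, 2]) > ncol(ref)
      if (any(diverged)) {
        ok[act[diverged]] <- FALSE
        solvable[act[diverged]] <- FALSE
      }
    }
    d <- dl * scale
  }
  out <- pts + d
  nr <- nrow(ref_pyr[[1]]); nc <- ncol(ref_pyr[[1]])
  inside <- out[, 1] >= 1 & out[, 1] <= nr & out[, 2] >= 1 & out[, 2] <= nc
  ok <- ok & inside & is.finite(out[, 1]) & is.finite(out[, 2])
  list(pos = out, ok = ok)
}

#' Select the reference frame by image correlation
#'
#' Among the already-segmented (candidate) frames, returns the one with
#' the highest zero-normalized cross-correlation with the current frame
#' over `region` — not necessarily the direct predecessor. Ties break to
#' the lowest candidate index.
#'
#' @param video an [ultrasound_video].
#' @param frame_index 1-based index of the current frame.
#' @param candidates integer vector of candidate frame indices.
#' @param region optional `c(row_min, row_max, col_min, col_max)`
#'   restricting the correlation to the segmentation's bounding region.
#' @return the selected candidate frame index.
#' @export
select_reference_frame <- function(video, frame_index, candidates,
                                   region = NULL) {
  if (length(candidates) == 0L) stop("candidate set is empty")
  candidates <- sort(unique(as.integer(candidates)))
  crop <- function(f) {
    if (is.null(region)) f else
      f[region[1]:region[2], region[3]:region[4], drop = FALSE]
  }
  cur <- crop(video$frames[[frame_index]])
  cors <- vapply(candidates,
                 function(k) zncc(cur, crop(video$frames[[k]])), numeric(1))
  candidates[which.max(cors)]
}

# Region (with margin) spanned by a segmentation, clamped to the image.
segmentation_region <- function(seg, margin = 10L) {
  b <- seg$boundaries
  c(max(1L, floor(min(b)) - margin),
    min(seg$img_dim[1], ceiling(max(b)) + margin),
    seg$col_start,
    seg$col_start + ncol(b) - 1L)
}

# 1-D fast global smoother: minimizes sum (x - y)^2 +
# lambda * sum w_i (x_i - x_{i+1})^2 with edge-aware weights, solved as
# a tridiagonal system. `guide` gives the intensity used for the edge
# weights.
fgs_smooth_1d <- function(y, lambda, sigma_edge, guide = NULL) {
  n <- length(y)
  if (n <= 2L || lambda <= 0) return(y)
  w <- if (is.null(guide)) rep(1, n - 1L) else
    exp(-abs(diff(guide)) / sigma_edge)
  lw <- lambda * w
  # tridiagonal (I + lambda D' W D)
  diag_main <- 1 + c(lw, 0) + c(0, lw)
  A <- diag(diag_main)
  for (i in seq_len(n - 1L)) {
    A[i, i + 1L] <- -lw[i]
    A[i + 1L, i] <- -lw[i]
  }
  as.numeric(solve(A, y))
}

#' Propagate keyframe segmentations to every frame
#'
#' For every non-key frame, the best-correlated keyframe is selected as
#' the reference, the boundary polylines are sampled, the samples are
#' tracked into the target frame with pyramidal Lucas-Kanade, the
#' vertical displacement field is post-filtered with the edge-aware fast
#' global smoother (`fgs_lambda`, `fgs_sigma`) and interpolated back to
#' every column. Boundary ordering is re-enforced by an order-preserving
#' projection (sort plus a minimal separation of 1 px).
#'
#' @param video an [ultrasound_video].
#' @param keyframe_segmentations list of [fascia_segmentation]s; their
#'   `frame_index` fields define the keyframes.
#' @param config a [tracker_config].
#' @param sample_stride column spacing of boundary samples tracked by
#'   the flow (pixels).
#' @return list of [fascia_segmentation], one per frame (keyframes keep
#'   their own, others have source `propagated`).
#' @export
propagate_segmentation <- function(video, keyframe_segmentations,
                                   config = tracker_config(),
                                   sample_stride = 16L) {
  if (inherits(keyframe_segmentations, "fascia_segmentation"))
    keyframe_segmentations <- list(keyframe_segmentations)
  if (length(keyframe_segmentations) == 0L)
    stop("at least one keyframe segmentation is required")
  keys <- vapply(keyframe_segmentations, `[[`, integer(1), "frame_index")
  names(keyframe_segmentations) <- as.character(keys)
  presmooth <- config$sigma * config$window
  key_pyr <- lapply(keyframe_segmentations, function(s)
    build_pyramid(video$frames[[s$frame_index]], config$levels, presmooth))
  region <- segmentation_region(keyframe_segmentations[[1]])

  nf <- n_frames(video)
  out <- vector("list", nf)
  for (k in keys) out[[k]] <- keyframe_segmentations[[as.character(k)]]
  rest <- setdiff(seq_len(nf), keys)
  refs <- vapply(rest, function(t)
    select_reference_frame(video, t, keys, region), integer(1))
  # process frames outward from their reference keyframe so that each
  # solve warm-starts from the adjacent, already-solved frame (the LK
  # template always stays the keyframe's: no drift accumulation)
  ord <- order(abs(rest - refs))
  warm_env <- new.env(parent = emptyenv())
  for (i in ord) {
    t <- rest[i]
    ref_idx <- refs[i]
    ref_seg <- keyframe_segmentations[[as.character(ref_idx)]]
    ref_pyr <- key_pyr[[as.character(ref_idx)]]
    wkey <- paste0(ref_idx, ".", if (t < ref_idx) "lo" else "hi")
    init_d <- if (exists(wkey, envir = warm_env)) get(wkey, envir = warm_env)
      else NULL
    cur_pyr <- build_pyramid(video$frames[[t]],
                             if (is.null(init_d)) config$levels else 1L,
                             presmooth)

    b <- ref_seg$boundaries
    w <- ncol(b)
    samp <- unique(c(seq(1L, w, by = sample_stride), w))
    ns <- length(samp)
    # all four boundaries tracked in one batched LK call
    pts <- cbind(as.vector(t(b[, samp])),
                 rep(ref_seg$col_start + samp - 1, times = 4L))
    tr <- lk_track(ref_pyr, cur_pyr, pts, config, init_d = init_d)
    assign(wkey, tr$pos - pts, envir = warm_env)
    new_b <- b
    for (k in 1:4) {
      sel <- (k - 1L) * ns + seq_len(ns)
      good <- tr$ok[sel]
      if (sum(good) < 2L)
        stop("optical-flow propagation failed at frame ", t,
             " (boundary ", k, "): too few trackable samples")
      dy <- tr$pos[sel[good], 1] - pts[sel[good], 1]
      dx <- tr$pos[sel[good], 2] - pts[sel[good], 2]
      guide <- bilinear_sample(video$frames[[ref_idx]],
                               pts[sel[good], 1], pts[sel[good], 2])
      dy_s <- fgs_smooth_1d(dy, config$fgs_lambda / 1000,
                            config$fgs_sigma, guide)
      dx_med <- stats::median(dx)
      dy_all <- stats::approx(samp[good], dy_s, xout = seq_len(w),
                              rule = 2)$y
      new_b[k, ] <- polyline_interp(b[k, ], seq_len(w) - dx_med) + dy_all
    }
    new_b <- pmin(pmax(new_b, 1), ref_seg$img_dim[1])
    new_b <- enforce_boundary_order(new_b, ref_seg$img_dim[1])
    out[[t]] <- fascia_segmentation(t, new_b, ref_seg$img_dim,
                                    ref_seg$col_start, source = "propagated")
  }
  out
}

#' Place the three measurement points per muscle
#'
#' Points are placed on the upper fascia of each muscle (OE, OI, TrA ->
#' boundaries 1, 2, 3) at 40%, 50% and 60% of the segmented column
#' range, i.e. around the middle of the fascia, with rows interpolated
#' from the boundary polyline.
#'
#' @param segmentation a [fascia_segmentation].
#' @return data.frame with columns `muscle`, `point_id` (0, 1, 2),
#'   `row`, `col` (1-based image coordinates).
#' @export
place_measurement_points <- function(segmentation) {
  b <- segmentation$boundaries
  w <- ncol(b)
  if (w < 5L) stop("column range too small to place measurement points")
  fracs <- c(0.4, 0.5, 0.6)
  local_col <- pmin(1 + round(fracs * w), w)
  out <- do.call(rbind, lapply(1:3, function(m)
    data.frame(muscle = MUSCLES[m], point_id = 0:2,
               row = polyline_interp(b[m, ], local_col),
               col = segmentation$col_start + local_col - 1)))
  attr(out, "placement_frame") <- segmentation$frame_index
  out
}

#' Track the measurement points through the video
#'
#' Every frame is matched against the keyframes by correlation; each
#' point is then tracked from the best reference keyframe into the
#' current frame with pyramidal Lucas-Kanade. Points that diverge or
#' leave the image are flagged (`flag = "lost"`), never silently
#' dropped.
#'
#' @param video an [ultrasound_video].
#' @param points measurement points (from [place_measurement_points()])
#'   placed on the keyframe(s); a list of such tables for multiple
#'   keyframes, each carrying its `placement_frame` attribute.
#' @param config a [tracker_config]; `keyframes` defaults to the
#'   placement frames of `points`.
#' @return data.frame: `frame`, `muscle`, `point_id`, `row`, `col`,
#'   `flag` (`"ok"` or `"lost"`).
#' @export
track_points <- function(video, points, config = tracker_config()) {
  if (is.data.frame(points)) points <- list(points)
  keys <- vapply(points, function(p) {
    k <- attr(p, "placement_frame")
    if (is.null(k)) stop("points table lacks its placement_frame attribute")
    as.integer(k)
  }, integer(1))
  names(points) <- as.character(keys)
  d <- frame_dim(video)
  for (p in points)
    if (any(p$row < 1 | p$row > d[1] | p$col < 1 | p$col > d[2]))
      stop("measurement point initialized outside the image")
  presmooth <- config$sigma * config$window
  key_pyr <- lapply(keys, function(k)
    build_pyramid(video$frames[[k]], config$levels, presmooth))
  names(key_pyr) <- as.character(keys)
  rmin <- max(1, floor(min(points[[1]]$row) - 20))
  rmax <- min(d[1], ceiling(max(points[[1]]$row) + 60))
  region <- c(rmin, rmax, 1, d[2])

  nf <- n_frames(video)
  res <- vector("list", nf)
  base <- points[[1]][, c("muscle", "point_id")]
  for (t in keys) {
    p <- points[[as.character(t)]]
    res[[t]] <- data.frame(frame = t, base, row = p$row, col = p$col,
                           flag = "ok")
  }
  rest <- setdiff(seq_len(nf), keys)
  refs <- vapply(rest, function(t)
    select_reference_frame(video, t, keys, region), integer(1))
  ord <- order(abs(rest - refs))  # outward from the reference keyframe
  warm_env <- new.env(parent = emptyenv())
  for (i in ord) {
    t <- rest[i]
    ref <- refs[i]
    p <- points[[as.character(ref)]]
    pts <- cbind(p$row, p$col)
    wkey <- paste0(ref, ".", if (t < ref) "lo" else "hi")
    init_d <- if (exists(wkey, envir = warm_env)) get(wkey, envir = warm_env)
      else NULL
    cur_pyr <- build_pyramid(video$frames[[t]],
                             if (is.null(init_d)) config$levels else 1L,
                             presmooth)
    tr <- lk_track(key_pyr[[as.character(ref)]], cur_pyr, pts, config,
                   init_d = init_d)
    assign(wkey, tr$pos - pts, envir = warm_env)
    flag <- ifelse(tr$ok, "ok", "lost")
    if (all(flag == "lost"))
      stop("all measurement points lost at frame ", t)
    if (any(flag == "lost"))
      warning(sum(flag == "lost"), " measurement point(s) lost at frame ", t)
    res[[t]] <- data.frame(frame = t, base, row = tr$pos[, 1],
                           col = tr$pos[, 2], flag = flag)
  }
  tracks <- do.call(rbind, res)
  rownames(tracks) <- NULL
  tracks
}

#' Write / read point tracks as CSV (0-based frame indices on disk)
#' @param tracks data.frame from [track_points()].
#' @param path CSV path.
#' @return the path (write) or the tracks data.frame (read), with
#'   1-based frame indices in R.
#' @export
write_tracks_csv <- function(tracks, path) {
  out <- tracks
  out$frame <- out$frame - 1L
  out$row <- out$row - 1
  out$col <- out$col - 1
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  out <- utils::read.csv(path)
  out$frame <- out$frame + 1L
  out$row <- out$row + 1
  out$col <- out$col + 1
  out
}
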