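# Minimal spot detection and frame-to-frame linking, so analyses can start
# from image stacks. A deliberately simple detector (Gaussian band-pass,
# local maxima, centroid refinement) and a greedy nearest-neighbour linker;
# linking quality is validated against simulator ground truth rather than
# against any particular multi-hypothesis tracker.

# separable Gaussian blur with edge renormalization
.gblur <- function(img, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(seq(-half, half), sd = sigma)
  kern <- kern / sum(kern)
  conv1 <- function(m) {
    out <- matrix(0, nrow(m), ncol(m))
    wt <- matrix(0, nrow(m), ncol(m))
    for (o in seq(-half, half)) {
      src <- seq_len(nrow(m)) - o
      ok <- src >= 1 & src <= nrow(m)
      out[ok, ] <- out[ok, ] + kern[o + half + 1L] * m[src[ok], , drop = FALSE]
      wt[ok, ] <- wt[ok, ] + kern[o + half + 1L]
    }
    out / wt
  }
  t(conv1(t(conv1(img))))
}

#' Detect fluorescent spots in a single frame
#'
#' Band-pass filters the image (difference of Gaussians at the PSF scale and
#' 3x the PSF scale), finds local maxima above a robust
#' signal-to-noise threshold, and refines each to sub-pixel precision by
#' intensity-weighted centroid in a window around the maximum.
#'
#' @param img Numeric matrix (one frame, `[ny, nx]`).
#' @param psf_sigma_px Expected PSF standard deviation in pixels (>= 1).
#' @param snr_threshold Detections must exceed `median + snr_threshold * mad`
#'   of the band-passed image.
#' @return Data frame `x_px, y_px, intensity` (pixel coordinates; the centre
#'   of pixel (i, j) is (j - 0.5, i - 0.5)).
#' @export
detect_spots <- function(img, psf_sigma_px = 1.5, snr_threshold = 5) {
  if (psf_sigma_px < 1) stop("psf_sigma_px must be >= 1 pixel")
  bp <- .gblur(img, psf_sigma_px) - .gblur(img, 3 * psf_sigma_px)
  thr <- stats::median(bp) + snr_threshold * stats::mad(bp)
  ny <- nrow(img); nx <- ncol(img)
  # 3x3 local maxima strictly above all neighbours (ties broken by position)
  pad <- matrix(-Inf, ny + 2L, nx + 2L)
  pad[2:(ny + 1L), 2:(nx + 1L)] <- bp
  ismax <- bp > thr
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ismax <- ismax & (bp >= pad[(2:(ny + 1L)) + di, (2:(nx + 1L)) + dj])
  }
  idx <- which(ismax, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(x_px = numeric(0), y_px = numeric(0),
                      intensity = numeric(0)))
  half <- max(2L, ceiling(2 * psf_sigma_px))
  res <- vector("list", nrow(idx))
  for (k in seq_len(nrow(idx))) {
    i0 <- idx[k, 1]; j0 <- idx[k, 2]
    is_ <- max(1L, i0 - half):min(ny, i0 + half)
    js <- max(1L, j0 - half):min(nx, j0 + half)
    w <- pmax(bp[is_, js, drop = FALSE], 0)
    tw <- sum(w)
    if (tw <= 0) next
    yc <- sum((is_ - 0.5) * rowSums(w)) / tw
    xc <- sum((js - 0.5) * colSums(w)) / tw
    res[[k]] <- data.frame(x_px = xc, y_px = yc, intensity = sum(w))
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out)) data.frame(x_px = numeric(0), y_px = numeric(0),
                               intensity = numeric(0)) else out
}

#' Detect spots in every frame of a stack
#'
#' @param stack Array `[ny, nx, n_frames]` (e.g. from [render_frames()] or
#'   [read_stack_tiff()]).
#' @param pixel_size Pixel size in um; output coordinates are um.
#' @param origin Lab-frame coordinate of the image corner (um).
#' @inheritParams detect_spots
#' @return Data frame `frame, x_um, y_um, intensity` (frames 0-based).
#' @export
detect_stack <- function(stack, psf_sigma_px = 1.5, snr_threshold = 5,
                         pixel_size = attr(stack, "pixel_size"),
                         origin = attr(stack, "origin")) {
  if (is.null(pixel_size)) pixel_size <- 1
  if (is.null(origin)) origin <- c(0, 0)
  out <- vector("list", dim(stack)[3])
  for (k in seq_len(dim(stack)[3])) {
    d <- detect_spots(stack[, , k], psf_sigma_px, snr_threshold)
    if (nrow(d))
      out[[k]] <- data.frame(frame = k - 1L,
                             x_um = origin[1] + d$x_px * pixel_size,
                             y_um = origin[2] + d$y_px * pixel_size,
                             intensity = d$intensity)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) data.frame(frame = integer(0), x_um = numeric(0),
                               y_um = numeric(0), intensity = numeric(0))
  else res
}

#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbour assignment between consecutive frames: candidate
#' (track head, detection) pairs within `max_disp` are accepted in order of
#' increasing distance, each detection and each head used at most once; ties
#' are broken by lowest detection index, so linking is deterministic.
#' Unmatched heads survive up to `max_gap` frames before the track is
#' closed. Output tracks are filtered to `min_steps` adjacent-frame steps.
#'
#' @param detections Data frame `frame, x_um, y_um` (0-based frames).
#' @param max_disp Maximum frame-to-frame displacement in um (> 0).
#' @param max_gap Frames a track may survive without a detection (default 0).
#' @param min_steps Minimum adjacent-frame steps per emitted track.
#' @param cell_id,channel Labels written into the output table.
#' @return A standard track table.
#' @export
link <- function(detections, max_disp, max_gap = 0L, min_steps = 5L,
                 cell_id = 1L, channel = "green") {
  if (max_disp <= 0) stop("max_disp must be > 0")
  det <- detections[order(detections$frame), , drop = FALSE]
  if (nrow(det) == 0)
    return(data.frame(cell_id = integer(0), track_id = integer(0),
                      channel = character(0), frame = integer(0),
                      x_um = numeric(0), y_um = numeric(0)))
  frames <- sort(unique(det$frame))
  # active track state: id, last x/y, last frame
  act <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                    last = integer(0))
  next_id <- 1L
  rows <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    d <- det[det$frame == f, , drop = FALSE]
    nd <- nrow(d)
    assigned <- rep(NA_integer_, nd)
    if (nrow(act) > 0 && nd > 0) {
      alive <- which(f - act$last <= max_gap + 1L)
      if (length(alive) > 0) {
        dm <- sqrt(outer(act$x[alive], d$x_um, "-")^2 +
                   outer(act$y[alive], d$y_um, "-")^2)
        cand <- which(dm <= max_disp, arr.ind = TRUE)
        if (nrow(cand) > 0) {
          # order by distance, then head index, then detection index
          o <- order(dm[cand], cand[, 1], cand[, 2])
          used_h <- logical(length(alive)); used_d <- logical(nd)
          for (ci in o) {
            h <- cand[ci, 1]; dd <- cand[ci, 2]
            if (used_h[h] || used_d[dd]) next
            used_h[h] <- TRUE; used_d[dd] <- TRUE
            assigned[dd] <- alive[h]
          }
        }
      }
    }
    for (dd in seq_len(nd)) {
      if (is.na(assigned[dd])) {
        act <- rbind(act, data.frame(id = next_id, x = d$x_um[dd],
                                     y = d$y_um[dd], last = f))
        tid <- next_id
        next_id <- next_id + 1L
      } else {
        h <- assigned[dd]
        act$x[h] <- d$x_um[dd]; act$y[h] <- d$y_um[dd]; act$last[h] <- f
        tid <- act$id[h]
      }
      rows[[length(rows) + 1L]] <- data.frame(cell_id = cell_id,
                                              track_id = tid,
                                              channel = channel, frame = f,
                                              x_um = d$x_um[dd],
                                              y_um = d$y_um[dd])
    }
    # drop heads beyond the gap allowance
    act <- act[f - act$last <= max_gap, , drop = FALSE]
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  suppressMessages(filter_min_steps(out, min_steps))
}
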