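# Rendering of synthetic image stacks: each localization becomes a 2D
# Gaussian PSF spot with Poisson shot noise over a constant background.

#' Render tracks into a synthetic image stack
#'
#' Each localization is drawn as an integrated 2D Gaussian spot of total
#' intensity `photon_rate` photons on a constant `background` (photons per
#' pixel); every pixel then receives Poisson shot noise. The field of view
#' is chosen to cover all localizations unless `fov_px` is given.
#'
#' @param tracks A track table (coordinates in um).
#' @param psf_sigma PSF standard deviation in um (> 0).
#' @param photon_rate Expected photons per spot per frame.
#' @param background Expected background photons per pixel per frame.
#' @param pixel_size Pixel size in um (> 0).
#' @param n_frames Number of frames; defaults to `max(frame) + 1`.
#' @param fov_px Optional integer c(nx, ny) field of view in pixels.
#' @param origin Lab-frame coordinate of the lower-left image corner in um;
#'   defaults to fit all localizations with a margin.
#' @return A numeric array `[ny, nx, n_frames]` of photon counts, with
#'   attributes `pixel_size` and `origin`.
#' @export
render_frames <- function(tracks, psf_sigma = 0.15, photon_rate = 500,
                          background = 5, pixel_size = 0.1,
                          n_frames = NULL, fov_px = NULL, origin = NULL) {
  if (psf_sigma <= 0) stop("psf_sigma must be > 0")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (is.null(n_frames))
    n_frames <- if (nrow(tracks)) max(tracks$frame) + 1L else 1L
  margin <- 4 * psf_sigma
  if (is.null(origin)) {
    origin <- if (nrow(tracks))
      c(min(tracks$x_um) - margin, min(tracks$y_um) - margin)
    else c(0, 0)
  }
  if (is.null(fov_px)) {
    if (nrow(tracks)) {
      nx <- ceiling((max(tracks$x_um) + margin - origin[1]) / pixel_size)
      ny <- ceiling((max(tracks$y_um) + margin - origin[2]) / pixel_size)
      fov_px <- c(max(nx, 8L), max(ny, 8L))
    } else fov_px <- c(32L, 32L)
  }
  nx <- fov_px[1]; ny <- fov_px[2]
  if (nrow(tracks)) {
    px <- (tracks$x_um - origin[1]) / pixel_size
    py <- (tracks$y_um - origin[2]) / pixel_size
    if (any(px < 0 | px > nx | py < 0 | py > ny))
      stop("localizations fall outside the field of view")
  }
  s_px <- psf_sigma / pixel_size
  half <- ceiling(4 * s_px)
  stack <- array(background, dim = c(ny, nx, n_frames))
  if (nrow(tracks)) {
    for (r in seq_len(nrow(tracks))) {
      fr <- tracks$frame[r] + 1L
      if (fr > n_frames) next
      x0 <- (tracks$x_um[r] - origin[1]) / pixel_size
      y0 <- (tracks$y_um[r] - origin[2]) / pixel_size
      xs <- max(1L, floor(x0) - half):min(nx, ceiling(x0) + half)
      ys <- max(1L, floor(y0) - half):min(ny, ceiling(y0) + half)
      # integrated Gaussian over pixel edges (pixel i spans [i-1, i])
      gx <- stats::pnorm(xs, x0, s_px) - stats::pnorm(xs - 1, x0, s_px)
      gy <- stats::pnorm(ys, y0, s_px) - stats::pnorm(ys - 1, y0, s_px)
      stack[ys, xs, fr] <- stack[ys, xs, fr] + photon_rate * outer(gy, gx)
    }
  }
  noisy <- array(stats::rpois(length(stack), stack), dim = dim(stack))
  attr(noisy, "pixel_size") <- pixel_size
  attr(noisy, "origin") <- origin
  noisy
}

#' Write an image stack as a multi-frame 16-bit TIFF
#'
#' @param stack Array `[ny, nx, n_frames]` of non-negative counts; values
#'   are stored as 16-bit unsigned integers (clipped at 65535).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  frames <- lapply(seq_len(dim(stack)[3]),
                   function(k) pmin(stack[, , k], 65535) / 65535)
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-frame TIFF into an image stack
#'
#' @param path TIFF path.
#' @return Array `[ny, nx, n_frames]` of counts (16-bit scale).
#' @export
read_stack_tiff <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  out <- array(0, dim = c(dim(frames[[1]])[1], dim(frames[[1]])[2],
                          length(frames)))
  for (k in seq_along(frames)) out[, , k] <- frames[[k]] * 65535
  out
}
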