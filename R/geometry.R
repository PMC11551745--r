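# Spherocylindrical cell geometry: a rectangle of length (L - 2r) capped by
# two half-discs of radius r, optionally rotated/translated in the lab frame.
# All coordinates are micrometres.

#' Create a spherocylindrical cell geometry
#'
#' Rod-shaped bacteria are modelled as 2D spherocylinders: a rectangle of
#' length `length - 2 * radius` capped by two half-discs of radius `radius`.
#' The geometry carries a lab-frame position (`cx`, `cy`) and the orientation
#' of the long axis (`theta`, radians).
#'
#' @param length Pole-to-pole length of the cell in micrometres. Must satisfy
#'   `length >= 2 * radius`.
#' @param radius Half-width of the cell in micrometres (> 0).
#' @param cx,cy Lab-frame coordinates of the cell centre (micrometres).
#' @param theta Orientation of the long axis in radians.
#' @return An object of class `cell_geometry`.
#' @examples
#' geom <- cell_geometry(length = 2.5, radius = 0.5)
#' in_cell(geom, 0, 0)
#' @export
cell_geometry <- function(length, radius, cx = 0, cy = 0, theta = 0) {
  stopifnot(is.numeric(length), is.numeric(radius), is.numeric(cx),
            is.numeric(cy), is.numeric(theta))
  if (!is.finite(length) || !is.finite(radius)) stop("geometry must be finite")
  if (radius <= 0) stop("cell radius must be > 0")
  if (length < 2 * radius) stop("cell length must be >= 2 * radius")
  structure(list(length = length, radius = radius, cx = cx, cy = cy,
                 theta = theta),
            class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf("cell_geometry: length %.3f um, radius %.3f um, centre (%.3f, %.3f), theta %.3f rad\n",
              x$length, x$radius, x$cx, x$cy, x$theta))
  invisible(x)
}

#' Transform lab-frame points into the cell frame
#'
#' In the cell frame the long axis is x, the origin is the cell centre, and
#' the poles sit at `x = +/- length/2`.
#'
#' @param geom A [cell_geometry()].
#' @param x,y Numeric vectors of lab-frame coordinates (micrometres).
#' @return A list with components `x` and `y` in the cell frame.
#' @export
to_cell_frame <- function(geom, x, y) {
  ct <- cos(geom$theta); st <- sin(geom$theta)
  dx <- x - geom$cx; dy <- y - geom$cy
  list(x = ct * dx + st * dy, y = -st * dx + ct * dy)
}

#' Transform cell-frame points back to the lab frame
#' @inheritParams to_cell_frame
#' @return A list with lab-frame components `x` and `y`.
#' @export
from_cell_frame <- function(geom, x, y) {
  ct <- cos(geom$theta); st <- sin(geom$theta)
  list(x = geom$cx + ct * x - st * y, y = geom$cy + st * x + ct * y)
}

# Signed distance to the spherocylinder wall (cell frame): negative inside.
# h is the half-length of the cylindrical midsection.
.spherocyl_dist <- function(geom, xc, yc) {
  h <- geom$length / 2 - geom$radius
  px <- pmin(pmax(xc, -h), h)
  sqrt((xc - px)^2 + yc^2) - geom$radius
}

#' Test whether lab-frame points lie inside the cell
#'
#' @inheritParams to_cell_frame
#' @param tol Tolerance in micrometres; points within `tol` outside the wall
#'   still count as inside.
#' @return Logical vector.
#' @export
in_cell <- function(geom, x, y, tol = 0) {
  cf <- to_cell_frame(geom, x, y)
  .spherocyl_dist(geom, cf$x, cf$y) <= tol
}

#' Reflect points into a cell by specular reflection at the wall
#'
#' Points outside the spherocylinder are mirrored across the nearest wall
#' point (the reflection preserves the uniform stationary distribution of
#' confined Brownian motion). Repeated until inside; pathological points far
#' outside are finally clamped just inside the wall.
#'
#' @inheritParams to_cell_frame
#' @param max_iter Maximum reflection passes.
#' @return A list with reflected lab-frame `x` and `y`.
#' @export
reflect_into_cell <- function(geom, x, y, max_iter = 25L) {
  cf <- to_cell_frame(geom, x, y)
  # points already inside are returned untouched (exact no-op)
  out0 <- .spherocyl_dist(geom, cf$x, cf$y) > 0
  if (!any(out0)) return(list(x = x, y = y))
  sub <- .reflect_into_cell_frame(geom, cf$x[out0], cf$y[out0], max_iter)
  lab <- from_cell_frame(geom, sub$x, sub$y)
  x[out0] <- lab$x; y[out0] <- lab$y
  list(x = x, y = y)
}

# reflection in the cell frame proper
.reflect_into_cell_frame <- function(geom, xc, yc, max_iter = 25L) {
  h <- geom$length / 2 - geom$radius
  r <- geom$radius
  for (i in seq_len(max_iter)) {
    px <- pmin(pmax(xc, -h), h)
    dx <- xc - px; dy <- yc
    d <- sqrt(dx^2 + dy^2)
    out <- which(d > r)
    if (length(out) == 0L) break
    # mirror across the wall: move from distance d to distance 2r - d
    sc <- (2 * r - d[out]) / d[out]
    xc[out] <- px[out] + dx[out] * sc
    yc[out] <- dy[out] * sc
  }
  # clamp any survivors (step much longer than the cell width)
  px <- pmin(pmax(xc, -h), h)
  dx <- xc - px; dy <- yc
  d <- sqrt(dx^2 + dy^2)
  out <- which(d > r)
  if (length(out) > 0L) {
    sc <- (r * 0.999) / d[out]
    xc[out] <- px[out] + dx[out] * sc
    yc[out] <- dy[out] * sc
  }
  list(x = xc, y = yc)
}

# Reflect points into a disc of radius r about (cx, cy); used for molecules
# tethered near a focus. Operates in the lab frame.
.reflect_into_disc <- function(cx, cy, r, x, y, max_iter = 25L) {
  dx <- x - cx; dy <- y - cy
  out0 <- which(dx^2 + dy^2 > r^2)
  if (length(out0) == 0L) return(list(x = x, y = y))
  dx <- dx[out0]; dy <- dy[out0]
  if (length(cx) > 1L) cx <- cx[out0]
  if (length(cy) > 1L) cy <- cy[out0]
  for (i in seq_len(max_iter)) {
    d <- sqrt(dx^2 + dy^2)
    out <- which(d > r)
    if (length(out) == 0L) break
    sc <- (2 * r - d[out]) / d[out]
    dx[out] <- dx[out] * sc
    dy[out] <- dy[out] * sc
  }
  d <- sqrt(dx^2 + dy^2)
  out <- which(d > r)
  if (length(out) > 0L) {
    sc <- (r * 0.999) / d[out]
    dx[out] <- dx[out] * sc
    dy[out] <- dy[out] * sc
  }
  x[out0] <- cx + dx
  y[out0] <- cy + dy
  list(x = x, y = y)
}

# Draw n points uniformly inside the cell (lab frame) by rejection sampling
# in the cell-frame bounding box.
.runif_in_cell <- function(geom, n) {
  if (n == 0L) return(list(x = numeric(0), y = numeric(0)))
  L2 <- geom$length / 2; r <- geom$radius
  xs <- numeric(0); ys <- numeric(0)
  while (length(xs) < n) {
    m <- max(2L * (n - length(xs)), 16L)
    cx <- stats::runif(m, -L2, L2)
    cy <- stats::runif(m, -r, r)
    keep <- .spherocyl_dist(geom, cx, cy) <= 0
    xs <- c(xs, cx[keep]); ys <- c(ys, cy[keep])
  }
  from_cell_frame(geom, xs[seq_len(n)], ys[seq_len(n)])
}
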