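# Spatial statistics: standardized-cell coordinates and track-density maps,
# dwelling (static) classification, focus detection from dwelling tracks,
# and nearest-focus distance-probability histograms.

# geometry lookup: data frame row -> cell_geometry
.geom_from_row <- function(g) {
  cell_geometry(g$length_um, g$radius_um, g$cx_um, g$cy_um, g$theta_rad)
}

#' Project localizations into standardized cell coordinates
#'
#' Rotates and translates points into the cell frame and scales them so that
#' the long axis spans [-0.5, 0.5] (poles at +/- 0.5) and the short axis
#' spans [-0.5, 0.5] (walls at +/- 0.5). Points farther than `tol_um`
#' outside the cell are dropped (count reported by message); surviving
#' coordinates are clamped into the unit cell.
#'
#' @param points Data frame with columns `x_um`, `y_um`.
#' @param geom A [cell_geometry()].
#' @param tol_um Tolerance outside the wall before a point is dropped.
#' @return Data frame with normalized columns `u` (long axis) and `v` (short
#'   axis), one row per retained point.
#' @export
standardize <- function(points, geom, tol_um = 0.1) {
  cf <- to_cell_frame(geom, points$x_um, points$y_um)
  dist <- .spherocyl_dist(geom, cf$x, cf$y)
  keep <- dist <= tol_um
  if (any(!keep))
    message(sprintf("standardize: dropped %d of %d points outside the cell",
                    sum(!keep), length(keep)))
  u <- pmin(pmax(cf$x[keep] / geom$length, -0.5), 0.5)
  v <- pmin(pmax(cf$y[keep] / (2 * geom$radius), -0.5), 0.5)
  data.frame(u = u, v = v)
}

#' Pooled track-density map in a standardized cell
#'
#' Projects all localizations of all tracks into standardized cell
#' coordinates, pools them over cells, and bins them on a regular grid. The
#' map is normalized to total probability 1; darker regions mark where
#' molecules spend more time (longer scanning). Optional Gaussian smoothing
#' (bandwidth in bins) regularizes sparse maps.
#'
#' @param tracks A track table.
#' @param geometries Per-cell geometry data frame (`cell_id, length_um,
#'   radius_um, cx_um, cy_um, theta_rad`).
#' @param grid_shape Integer c(n_long, n_short) bins along the long and
#'   short axes.
#' @param smooth_bins Gaussian smoothing bandwidth in bins (0 = off).
#' @return An object of class `cell_map`: list with `density` matrix
#'   (n_long x n_short, sums to 1), bin `u_edges`, `v_edges`, and `n_cells`.
#' @export
density_map <- function(tracks, geometries, grid_shape = c(40L, 20L),
                        smooth_bins = 1) {
  if (nrow(tracks) == 0) stop("density_map needs at least one track")
  pts <- vector("list", nrow(geometries))
  for (i in seq_len(nrow(geometries))) {
    g <- .geom_from_row(geometries[i, ])
    sel <- tracks$cell_id == geometries$cell_id[i]
    if (!any(sel)) next
    pts[[i]] <- suppressMessages(standardize(tracks[sel, ], g))
  }
  pts <- do.call(rbind, pts[!vapply(pts, is.null, logical(1))])
  if (is.null(pts) || nrow(pts) == 0) stop("no localizations inside any cell")
  ue <- seq(-0.5, 0.5, length.out = grid_shape[1] + 1L)
  ve <- seq(-0.5, 0.5, length.out = grid_shape[2] + 1L)
  ui <- pmin(findInterval(pts$u, ue, rightmost.closed = TRUE), grid_shape[1])
  vi <- pmin(findInterval(pts$v, ve, rightmost.closed = TRUE), grid_shape[2])
  dens <- matrix(0, grid_shape[1], grid_shape[2])
  for (r in seq_len(nrow(pts))) dens[ui[r], vi[r]] <- dens[ui[r], vi[r]] + 1
  if (smooth_bins > 0) {
    half <- max(1L, ceiling(3 * smooth_bins))
    kern <- stats::dnorm(seq(-half, half), sd = smooth_bins)
    kern <- kern / sum(kern)
    # separable convolution with edge renormalization
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
    dens <- t(conv1(t(conv1(dens))))
  }
  dens <- dens / sum(dens)
  structure(list(density = dens, u_edges = ue, v_edges = ve,
                 n_cells = length(unique(tracks$cell_id))),
            class = "cell_map")
}

#' @export
print.cell_map <- function(x, ...) {
  cat(sprintf("cell_map: %d x %d grid pooled over %d cells (total mass %.3f)\n",
              nrow(x$density), ncol(x$density), x$n_cells, sum(x$density)))
  invisible(x)
}

#' Classify tracks as static (dwelling) or mobile
#'
#' A track is static if at least `min_fraction` of its localizations lie
#' within `confinement_radius` of the track centroid — an explicit
#' operationalization of the dwelling events used to mark bound molecules
#' (e.g. replisome-engaged DnaX). Deterministic.
#'
#' @param tracks A track table.
#' @param confinement_radius Radius around the track centroid in um
#'   (default 0.09, i.e. 3 x a 30 nm localization error).
#' @param min_fraction Minimum fraction of points inside the radius
#'   (default 0.8).
#' @return Data frame with one row per track: `cell_id, track_id, channel,
#'   n_points, label` where label is "static" or "mobile".
#' @export
classify_dwelling <- function(tracks, confinement_radius = 0.09,
                              min_fraction = 0.8) {
  key <- interaction(tracks$cell_id, tracks$track_id, tracks$channel,
                     drop = TRUE)
  ids <- !duplicated(key)
  per <- split(tracks[, c("x_um", "y_um")], key)
  lab <- vapply(per, function(d) {
    cx <- mean(d$x_um); cy <- mean(d$y_um)
    r <- sqrt((d$x_um - cx)^2 + (d$y_um - cy)^2)
    if (mean(r <= confinement_radius) >= min_fraction) "static" else "mobile"
  }, character(1))
  out <- data.frame(cell_id = tracks$cell_id[ids],
                    track_id = tracks$track_id[ids],
                    channel = tracks$channel[ids],
                    n_points = as.integer(table(key)[as.character(key[ids])]),
                    label = lab[as.character(key[ids])],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Derive replisome foci from dwelling tracks
#'
#' Each static (dwelling) track contributes its centroid as a candidate
#' focus; centroids in the same cell closer than `merge_radius` are merged
#' by averaging (single-linkage), yielding a single fixed reference point
#' per focus.
#'
#' @param tracks A track table (typically the red / DnaX channel).
#' @param labels Output of [classify_dwelling()] for `tracks`; computed with
#'   defaults if omitted.
#' @param merge_radius Centroid merge distance in um (default 0.15).
#' @return A focus table `cell_id, focus_id, x_um, y_um`; empty input yields
#'   an empty table.
#' @export
foci_from_dwelling <- function(tracks, labels = NULL, merge_radius = 0.15) {
  empty <- data.frame(cell_id = integer(0), focus_id = integer(0),
                      x_um = numeric(0), y_um = numeric(0))
  if (nrow(tracks) == 0) return(empty)
  if (is.null(labels)) labels <- classify_dwelling(tracks)
  static <- labels[labels$label == "static", , drop = FALSE]
  if (nrow(static) == 0) return(empty)
  out <- vector("list", 0)
  for (cid in unique(static$cell_id)) {
    sc <- static[static$cell_id == cid, ]
    cents <- t(vapply(seq_len(nrow(sc)), function(i) {
      sel <- tracks$cell_id == cid & tracks$track_id == sc$track_id[i] &
        tracks$channel == sc$channel[i]
      c(mean(tracks$x_um[sel]), mean(tracks$y_um[sel]))
    }, numeric(2)))
    # single-linkage merge of centroids within merge_radius
    grp <- if (nrow(cents) == 1L) 1L else
      stats::cutree(stats::hclust(stats::dist(cents), method = "single"),
                    h = merge_radius)
    fx <- tapply(cents[, 1], grp, mean)
    fy <- tapply(cents[, 2], grp, mean)
    out[[length(out) + 1L]] <- data.frame(cell_id = cid,
                                          focus_id = seq_along(fx),
                                          x_um = as.numeric(fx),
                                          y_um = as.numeric(fy))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Distances from track points to the nearest focus
#'
#' For each track, takes its first `points_per_track` localizations (or
#' `points_per_track` evenly spaced ones with `mode = "even"`); for each
#' point computes the Euclidean distance
#' `D = sqrt((x_focus - x_i)^2 + (y_focus - y_i)^2)` to every focus in the
#' same cell and keeps the minimum (ties broken by lowest focus_id). Tracks
#' in cells without foci are skipped with a message. Cross-cell matching is
#' forbidden by construction.
#'
#' @param tracks A track table.
#' @param foci A focus table `cell_id, focus_id, x_um, y_um`.
#' @param points_per_track Number of points taken per track (default 5).
#' @param mode `"first"` (default) or `"even"` point selection.
#' @return Data frame `cell_id, track_id, point_index, distance_um,
#'   focus_id` with one row per (track, point).
#' @export
nearest_focus_distances <- function(tracks, foci, points_per_track = 5L,
                                    mode = c("first", "even")) {
  mode <- match.arg(mode)
  if (nrow(foci) == 0) stop("no foci supplied")
  key <- interaction(tracks$cell_id, tracks$track_id, tracks$channel,
                     drop = TRUE)
  per <- split(tracks, key)
  rows <- vector("list", length(per))
  skipped <- 0L
  for (j in seq_along(per)) {
    d <- per[[j]][order(per[[j]]$frame), ]
    fc <- foci[foci$cell_id == d$cell_id[1], , drop = FALSE]
    if (nrow(fc) == 0) { skipped <- skipped + 1L; next }
    np <- min(points_per_track, nrow(d))
    sel <- if (mode == "first") seq_len(np)
           else unique(round(seq(1, nrow(d), length.out = np)))
    dd <- d[sel, ]
    fc <- fc[order(fc$focus_id), ]
    dm <- outer(dd$x_um, fc$x_um, "-")^2 + outer(dd$y_um, fc$y_um, "-")^2
    wi <- apply(dm, 1, which.min)   # which.min takes the first (lowest id) tie
    rows[[j]] <- data.frame(cell_id = dd$cell_id, track_id = dd$track_id,
                            point_index = seq_along(sel),
                            distance_um = sqrt(dm[cbind(seq_along(wi), wi)]),
                            focus_id = fc$focus_id[wi])
  }
  if (skipped > 0)
    message(sprintf("nearest_focus_distances: skipped %d tracks in cells without foci",
                    skipped))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) stop("no track had a focus in its cell")
  rownames(out) <- NULL
  out
}

#' Probability histogram of nearest-focus distances
#'
#' Bins distances into equal-width bins of `bin_width` um over
#' [0, max distance] and normalizes to probability (bins sum to 1). This is
#' the distance-probability histogram used to quantify proximity of tracked
#' complexes to replication forks.
#'
#' @param distances Numeric vector of distances in um, or the data frame
#'   from [nearest_focus_distances()].
#' @param bin_width Bin width in um (default 0.1).
#' @param condition Optional condition label column.
#' @return Data frame `bin_left_um, bin_right_um, probability, condition`.
#' @export
distance_probability_histogram <- function(distances, bin_width = 0.1,
                                           condition = NA_character_) {
  if (is.data.frame(distances)) distances <- distances$distance_um
  if (length(distances) == 0) stop("no distances supplied")
  if (any(distances < 0)) stop("distances must be >= 0")
  top <- max(distances)
  edges <- seq(0, max(bin_width, ceiling(top / bin_width) * bin_width),
               by = bin_width)
  cnt <- graphics::hist(distances, breaks = edges, include.lowest = TRUE,
                        plot = FALSE)$counts
  data.frame(bin_left_um = edges[-length(edges)], bin_right_um = edges[-1],
             probability = cnt / sum(cnt), condition = condition)
}
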