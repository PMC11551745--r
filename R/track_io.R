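# Readers and writers for the plain-text interchange tables: track tables,
# cell geometries, focus sets, and analysis result tables. All coordinates
# are micrometres in the lab frame; frames are 0-based integers.

.track_cols <- c("cell_id", "track_id", "channel", "frame", "x_um", "y_um")

# Infer the field separator from the header line (tab or comma).
.detect_sep <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (length(hdr) == 0L) return("\t")
  if (grepl("\t", hdr)) "\t" else ","
}

#' Read a track table
#'
#' Reads a delimited text file with columns
#' `cell_id, track_id, channel, frame, x_um, y_um` (tab- or comma-separated,
#' header required; `channel` optional and defaulted to "green"). Rows are
#' grouped by (cell_id, track_id, channel) and sorted by frame; duplicate
#' frames within a track and non-finite coordinates are errors.
#'
#' @param path Path to the file.
#' @param delta_t Frame interval in seconds, attached as the `delta_t`
#'   attribute of the returned table.
#' @return A data frame of localizations with attribute `delta_t`. A message
#'   reports the number of rows read.
#' @export
read_tracks <- function(path, delta_t = 0.030) {
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!"channel" %in% names(df)) df$channel <- "green"
  missing <- setdiff(.track_cols, names(df))
  if (length(missing))
    stop("track table is missing columns: ", paste(missing, collapse = ", "))
  df <- df[.track_cols]
  if (nrow(df) > 0) {
    if (!is.numeric(df$x_um) || !is.numeric(df$y_um) ||
        any(!is.finite(df$x_um)) || any(!is.finite(df$y_um)))
      stop("non-numeric or non-finite coordinates in track table")
    if (any(df$frame < 0)) stop("negative frame index in track table")
    df <- df[order(df$cell_id, df$track_id, df$channel, df$frame), ,
             drop = FALSE]
    key <- paste(df$cell_id, df$track_id, df$channel, df$frame, sep = "\r")
    if (anyDuplicated(key)) {
      bad <- df[duplicated(key), , drop = FALSE][1, ]
      stop(sprintf("duplicated frame %d in track %s (cell %s)",
                   bad$frame, bad$track_id, bad$cell_id))
    }
    rownames(df) <- NULL
  }
  attr(df, "delta_t") <- delta_t
  message(sprintf("read %d localizations from %s", nrow(df), path))
  df
}

#' Write a track table
#'
#' @param tracks Data frame with the standard track columns.
#' @param path Output path; tab-separated with header.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(all(.track_cols %in% names(tracks)))
  utils::write.table(tracks[.track_cols], path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read / write cell geometry tables
#'
#' Geometry tables have one row per cell:
#' `cell_id, length_um, radius_um, cx_um, cy_um, theta_rad`.
#'
#' @param path File path.
#' @return `read_geometries` returns the data frame; `write_geometries`
#'   returns `path` invisibly.
#' @export
read_geometries <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .detect_sep(path),
                          stringsAsFactors = FALSE)
  need <- c("cell_id", "length_um", "radius_um", "cx_um", "cy_um", "theta_rad")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("geometry table is missing columns: ", paste(missing, collapse = ", "))
  df[need]
}

#' @rdname read_geometries
#' @param geometries Data frame of per-cell geometries.
#' @export
write_geometries <- function(geometries, path) {
  utils::write.table(geometries, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read / write focus tables
#'
#' Focus tables have one row per focus: `cell_id, focus_id, x_um, y_um`.
#'
#' @param path File path.
#' @return `read_foci` returns the data frame; `write_foci` returns `path`
#'   invisibly.
#' @export
read_foci <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .detect_sep(path),
                          stringsAsFactors = FALSE)
  need <- c("cell_id", "focus_id", "x_um", "y_um")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("focus table is missing columns: ", paste(missing, collapse = ", "))
  df[need]
}

#' @rdname read_foci
#' @param foci Data frame of focus positions.
#' @export
write_foci <- function(foci, path) {
  utils::write.table(foci, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Number of adjacent-frame steps per track (gaps do not count as steps).
.steps_per_track <- function(tracks) {
  if (nrow(tracks) == 0)
    return(data.frame(cell_id = integer(0), track_id = integer(0),
                      channel = character(0), n_steps = integer(0)))
  key <- interaction(tracks$cell_id, tracks$track_id, tracks$channel,
                     drop = TRUE)
  spl <- split(tracks$frame, key)
  ns <- vapply(spl, function(fr) sum(diff(sort(fr)) == 1L), integer(1))
  ids <- do.call(rbind, strsplit(names(spl), ".", fixed = TRUE))
  data.frame(cell_id = ids[, 1], track_id = ids[, 2], channel = ids[, 3],
             n_steps = as.integer(ns), stringsAsFactors = FALSE)
}

#' Keep only tracks with a minimum number of steps
#'
#' A "step" is an adjacent-frame displacement (frames differing by exactly
#' one); a track with n localizations and no gaps has n - 1 steps. The
#' default of five steps is the standard minimum track length for
#' single-molecule diffusion analysis. Set `count = "points"` to interpret
#' the threshold as a minimum number of localizations instead.
#'
#' @param tracks A track table.
#' @param min_steps Minimum number of steps (or points) required.
#' @param count Either `"steps"` (adjacent-frame displacements, default) or
#'   `"points"` (localizations).
#' @return The filtered track table (same attributes); a message reports how
#'   many tracks were retained and dropped.
#' @export
filter_min_steps <- function(tracks, min_steps = 5L, count = c("steps", "points")) {
  count <- match.arg(count)
  stopifnot(min_steps >= 1L)
  if (nrow(tracks) == 0) return(tracks)
  key <- interaction(tracks$cell_id, tracks$track_id, tracks$channel,
                     drop = TRUE)
  val <- if (count == "steps") {
    unsplit(lapply(split(tracks$frame, key),
                   function(fr) rep(sum(diff(sort(fr)) == 1L), length(fr))), key)
  } else {
    stats::ave(tracks$frame, key, FUN = length)
  }
  keep <- val >= min_steps
  n_tracks <- length(unique(key))
  n_kept <- length(unique(key[keep]))
  message(sprintf("filter_min_steps: retained %d of %d tracks (dropped %d)",
                  n_kept, n_tracks, n_tracks - n_kept))
  out <- tracks[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "delta_t") <- attr(tracks, "delta_t")
  out
}

#' Write an analysis result table
#'
#' Writes any result data frame (mixture fits, MSD curves, histograms) as
#' tab-separated text with a self-describing header; [read_results()] reads
#' it back losslessly.
#'
#' @param table A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Turn a mixture fit into a tidy per-component table
#'
#' @param fit A `mixture_fit` (see [fit_sqd_mixture()]).
#' @param condition Optional condition label added as a column.
#' @return Data frame with one row per component: `component, fraction,
#'   D_um2_s, sigma_um`, plus fit diagnostics.
#' @export
fit_table <- function(fit, condition = NA_character_) {
  stopifnot(inherits(fit, "mixture_fit"))
  data.frame(condition = condition,
             component = seq_len(fit$K),
             fraction = fit$fractions,
             D_um2_s = fit$D,
             sigma_um = fit$sigma,
             max_abs_residual = fit$max_abs_residual,
             converged = fit$converged,
             method = fit$method)
}
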