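# Figure vocabulary of the analysis: jump-distance histograms with fitted
# mixture curves and residual panels, bubble plots (fraction vs D), MSD
# curves with SEM bars, standardized-cell heat maps, and nearest-focus
# distance histograms. All return ggplot objects.

#' Jump-distance histogram with fitted mixture components
#'
#' Plots the jump-distance probability histogram stored in a fit's residual
#' table, the fitted total mixture curve and the per-component curves
#' (slow/intermediate/mobile in salmon, green and dark grey), plus a
#' residual panel. The residual panel's guide lines mark +/- 0.02, the
#' conventional bound for a statistically adequate fit.
#'
#' @param fit A `mixture_fit` from [fit_sqd_mixture()].
#' @param title Plot title.
#' @return A ggplot object (histogram and residual panel, stacked).
#' @export
plot_jump_histogram <- function(fit, title = "Jump-distance distribution") {
  res <- fit$residuals
  mid <- (res$bin_left_um + res$bin_right_um) / 2
  a <- 2 * fit$sigma^2  # exponential mean of r^2 per component
  comp <- do.call(rbind, lapply(seq_len(fit$K), function(i) {
    p <- fit$fractions[i] *
      (exp(-res$bin_left_um^2 / a[i]) - exp(-res$bin_right_um^2 / a[i]))
    data.frame(mid = mid, p = p, component = factor(i))
  }))
  pal <- c("salmon", "forestgreen", "grey25", "steelblue", "orchid")
  top <- ggplot2::ggplot(res, ggplot2::aes(x = mid)) +
    ggplot2::geom_col(ggplot2::aes(y = observed), fill = "grey85",
                      colour = "grey60", width = diff(res$bin_left_um[1:2])) +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(y = p, colour = component), linewidth = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = fitted), colour = "black",
                       linewidth = 0.9) +
    ggplot2::scale_colour_manual(values = pal[seq_len(fit$K)]) +
    ggplot2::labs(x = "jump distance (µm)", y = "probability",
                  title = title) +
    ggplot2::theme_classic()
  bottom <- ggplot2::ggplot(res, ggplot2::aes(x = mid, y = residual)) +
    ggplot2::geom_hline(yintercept = c(-0.02, 0.02), linetype = 2,
                        colour = "grey50") +
    ggplot2::geom_col(fill = "grey40", width = diff(res$bin_left_um[1:2])) +
    ggplot2::coord_cartesian(ylim = c(-0.025, 0.025)) +
    ggplot2::labs(x = "jump distance (µm)", y = "residual") +
    ggplot2::theme_classic()
  list(histogram = top, residuals = bottom)
}

#' Bubble plot of population fractions versus diffusion coefficients
#'
#' @param fits Named list of `mixture_fit` objects (one per condition).
#' @return A ggplot object: D on the y axis (log scale), conditions on x,
#'   bubble area proportional to the population fraction.
#' @export
plot_bubble <- function(fits) {
  if (inherits(fits, "mixture_fit")) fits <- list(fit = fits)
  df <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(condition = nm, D = f$D, fraction = f$fractions,
               component = factor(seq_len(f$K)))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = condition, y = D, size = fraction,
                                   colour = component)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_size_area(max_size = 14) +
    ggplot2::scale_colour_manual(values = c("salmon", "forestgreen", "grey25",
                                            "steelblue", "orchid")) +
    ggplot2::labs(y = "D (µm²/s)", x = NULL,
                  title = "Population sizes and diffusion constants") +
    ggplot2::theme_classic()
}

#' MSD-versus-time-lag plot with SEM error bars
#'
#' @param curves A single `msd_curve` or a named list of them.
#' @return A ggplot object.
#' @export
plot_msd <- function(curves) {
  if (inherits(curves, "msd_curve")) curves <- list(msd = curves)
  df <- do.call(rbind, lapply(names(curves), function(nm)
    cbind(as.data.frame(curves[[nm]]), condition = nm)))
  ggplot2::ggplot(df, ggplot2::aes(x = lag_s, y = msd_um2,
                                   colour = condition)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = msd_um2 - sem_um2,
                                        ymax = msd_um2 + sem_um2),
                           width = 0) +
    ggplot2::labs(x = "time lag (s)", y = "MSD (µm²)",
                  title = "Mean squared displacement") +
    ggplot2::theme_classic()
}

#' Standardized-cell track-density heat map
#'
#' @param map A `cell_map` from [density_map()].
#' @return A ggplot object; darker regions carry more track density.
#' @export
plot_density_map <- function(map) {
  uc <- (map$u_edges[-1] + map$u_edges[-length(map$u_edges)]) / 2
  vc <- (map$v_edges[-1] + map$v_edges[-length(map$v_edges)]) / 2
  df <- expand.grid(u = uc, v = vc)
  df$density <- as.vector(map$density)
  ggplot2::ggplot(df, ggplot2::aes(x = u, y = v, fill = density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkblue") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "long axis (normalized)", y = "short axis (normalized)",
                  title = sprintf("Track density (%d cells)", map$n_cells)) +
    ggplot2::theme_classic()
}

#' Nearest-focus distance probability histogram
#'
#' @param hist_df One or more histogram tables from
#'   [distance_probability_histogram()] (row-bound; the `condition` column
#'   separates conditions).
#' @return A ggplot object with side-by-side bars per condition.
#' @export
plot_distance_histogram <- function(hist_df) {
  hist_df$mid <- (hist_df$bin_left_um + hist_df$bin_right_um) / 2
  ggplot2::ggplot(hist_df,
                  ggplot2::aes(x = mid, y = probability,
                               fill = factor(condition))) +
    ggplot2::geom_col(position = "dodge",
                      width = diff(hist_df$bin_left_um[1:2]) * 0.9) +
    ggplot2::scale_fill_manual(values = c("forestgreen", "salmon", "grey40"),
                               name = "condition") +
    ggplot2::labs(x = "distance to nearest focus (µm)",
                  y = "probability",
                  title = "Proximity to replisome foci") +
    ggplot2::theme_classic()
}
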