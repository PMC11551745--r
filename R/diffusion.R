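# Diffusion statistics for single-molecule tracks: frame-to-frame
# displacement samples, zero-mean Gaussian mixture fits (EM), jump-distance
# (squared-displacement) mixture fits on the empirical CDF, global fits with
# shared diffusion constants across conditions, and MSD analysis.
#
# For 2D Brownian motion with diffusion coefficient D observed at frame
# interval dt with localization error s_loc per coordinate:
#   per-coordinate step  ~ N(0, 2 D dt + 2 s_loc^2)
#   squared 2D jump r^2  ~ Exp(mean = 4 D dt + 4 s_loc^2)
#   MSD(k dt)            = 4 D k dt + 4 s_loc^2
# and a population's step standard deviation sigma maps to D = sigma^2/(2 dt).

# split a track table into per-track data frames ordered by frame
.split_tracks <- function(tracks) {
  key <- interaction(tracks$cell_id, tracks$track_id, tracks$channel,
                     drop = TRUE)
  lapply(split(tracks[, c("frame", "x_um", "y_um")], key),
         function(d) d[order(d$frame), , drop = FALSE])
}

# adjacent-frame (lag-1) displacement pairs; gapped pairs are excluded
.adjacent_steps <- function(tracks) {
  if (nrow(tracks) == 0)
    return(data.frame(dx = numeric(0), dy = numeric(0)))
  per <- lapply(.split_tracks(tracks), function(d) {
    if (nrow(d) < 2) return(NULL)
    adj <- which(diff(d$frame) == 1L)
    if (length(adj) == 0) return(NULL)
    data.frame(dx = d$x_um[adj + 1L] - d$x_um[adj],
               dy = d$y_um[adj + 1L] - d$y_um[adj])
  })
  out <- do.call(rbind, per[!vapply(per, is.null, logical(1))])
  if (is.null(out)) data.frame(dx = numeric(0), dy = numeric(0)) else out
}

#' Pooled 1D frame-to-frame displacements
#'
#' Collects the signed adjacent-frame displacements of all molecules, with x
#' and y contributing separate observations (sample size = 2 x number of
#' adjacent-frame pairs). Only frames differing by exactly one enter; gapped
#' pairs are excluded.
#'
#' @param tracks A track table.
#' @return Numeric vector of 1D displacements in um.
#' @export
frame_displacements <- function(tracks) {
  st <- .adjacent_steps(tracks)
  if (nrow(st) == 0) stop("no adjacent-frame pairs in input tracks")
  c(st$dx, st$dy)
}

#' Squared 2D frame-to-frame displacements
#'
#' `r^2 = dx^2 + dy^2` per adjacent-frame pair; the square root of this
#' sample is the jump-distance distribution.
#'
#' @param tracks A track table.
#' @return Numeric vector of squared displacements in um^2.
#' @export
squared_displacements <- function(tracks) {
  st <- .adjacent_steps(tracks)
  st$dx^2 + st$dy^2
}

#' Convert a step standard deviation to a diffusion coefficient
#'
#' Applies `D = sigma^2 / (2 * delta_t)`, the standard conversion from a
#' population's 1D per-frame step standard deviation to its diffusion
#' coefficient.
#'
#' @param sigma Step standard deviation in um (>= 0).
#' @param delta_t Frame interval in seconds (> 0).
#' @return Diffusion coefficient in um^2/s.
#' @examples
#' sigma_to_D(0.037147, 0.030)  # ~0.023 um^2/s
#' @export
sigma_to_D <- function(sigma, delta_t) {
  if (any(delta_t <= 0)) stop("delta_t must be > 0")
  if (any(sigma < 0)) stop("sigma must be >= 0")
  sigma^2 / (2 * delta_t)
}

# -- mixture_fit container ---------------------------------------------------

.mixture_fit <- function(K, fractions, sigma, delta_t, method,
                         loglik = NA_real_, sse = NA_real_,
                         converged = TRUE, warning = NA_character_,
                         residuals = NULL, D = NULL, d_clipped = FALSE) {
  ord <- order(sigma)
  fractions <- fractions[ord]; sigma <- sigma[ord]
  if (is.null(D)) D <- sigma_to_D(sigma, delta_t) else D <- D[ord]
  structure(list(K = K, fractions = fractions, sigma = sigma, D = D,
                 delta_t = delta_t, method = method, loglik = loglik,
                 sse = sse, converged = converged, warning = warning,
                 residuals = residuals,
                 max_abs_residual = if (is.null(residuals)) NA_real_
                                    else max(abs(residuals$residual)),
                 d_clipped = d_clipped),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("mixture_fit (%s), K = %d, delta_t = %g s\n",
              x$method, x$K, x$delta_t))
  for (i in seq_len(x$K))
    cat(sprintf("  component %d: f = %.3f, D = %.4g um^2/s, sigma = %.4g um\n",
                i, x$fractions[i], x$D[i], x$sigma[i]))
  if (!is.na(x$max_abs_residual))
    cat(sprintf("  max |histogram residual| = %.4f\n", x$max_abs_residual))
  if (!is.na(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}

# residuals of a probability histogram against a fitted jump-distance
# mixture: bins span [0, 99.5th percentile] of r, probabilities are counts/n
.jump_residuals <- function(r, a, fractions, n_bins = 50L) {
  edges <- seq(0, stats::quantile(r, 0.995, names = FALSE), length.out = n_bins + 1L)
  if (edges[n_bins + 1L] <= 0) edges <- seq(0, max(r[1], 1e-9), length.out = n_bins + 1L)
  cnt <- graphics::hist(r, breaks = c(edges, Inf), plot = FALSE)$counts[seq_len(n_bins)]
  obs <- cnt / length(r)
  # P(r <= b) = 1 - sum_i f_i exp(-b^2 / a_i)
  cdf <- function(b) 1 - colSums(fractions * exp(-outer(1 / a, b^2)))
  fitted <- diff(cdf(edges))
  data.frame(bin_left_um = edges[-(n_bins + 1L)], bin_right_um = edges[-1L],
             observed = obs, fitted = fitted, residual = obs - fitted)
}

# residuals of a displacement-histogram against a zero-mean Gaussian mixture
.gauss_residuals <- function(x, sigma, fractions, n_bins = 50L) {
  lim <- stats::quantile(abs(x), 0.995, names = FALSE)
  if (lim <= 0) lim <- max(abs(x), 1e-9)
  edges <- seq(-lim, lim, length.out = n_bins + 1L)
  cnt <- graphics::hist(pmin(pmax(x, -lim), lim), breaks = edges,
                        plot = FALSE)$counts
  obs <- cnt / length(x)
  cdf <- function(b) colSums(fractions * t(outer(b, pmax(sigma, 1e-12),
                                                 stats::pnorm, mean = 0)))
  fitted <- diff(cdf(edges))
  data.frame(bin_left_um = edges[-(n_bins + 1L)], bin_right_um = edges[-1L],
             observed = obs, fitted = fitted, residual = obs - fitted)
}

#' Fit a zero-mean Gaussian mixture to 1D displacements
#'
#' Maximum-likelihood fit of K zero-mean Gaussian components to the pooled
#' frame-to-frame displacement sample via expectation-maximization, the
#' standard static/mobile decomposition (K = 2) of single-molecule
#' displacement data. Initialization uses quantile-spread sigma seeds with
#' deterministic multiplicative jitters (multi-start, best likelihood kept),
#' so the fit is fully deterministic.
#'
#' @param displacements Numeric vector of signed 1D displacements (um), as
#'   produced by [frame_displacements()].
#' @param K Number of components (default 2).
#' @param delta_t Frame interval in seconds; used to report
#'   `D_i = sigma_i^2 / (2 delta_t)`.
#' @param n_starts Number of EM restarts (>= 1).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return A `mixture_fit` with components sorted by ascending D, histogram
#'   residuals (50 bins), log-likelihood, BIC (for manual selection of K)
#'   and convergence flag. A degenerate sample (all values identical) yields
#'   a flagged single-component result.
#' @export
fit_gaussian_mixture <- function(displacements, K = 2L, delta_t = 0.030,
                                 n_starts = 5L, max_iter = 1000L, tol = 1e-10) {
  x <- displacements[is.finite(displacements)]
  n <- length(x)
  if (n < 10L * K) stop("need at least 10*K displacements")
  if (stats::sd(x) == 0) {
    res <- .gauss_residuals(x, abs(x[1]), 1)
    return(.mixture_fit(1L, 1, abs(x[1]) * 0, delta_t, "gaussian_em",
                        converged = TRUE, warning = "degenerate sample",
                        residuals = res))
  }
  s0 <- stats::sd(x)
  x2 <- x^2
  em <- function(sig0) {
    f <- rep(1 / K, K); sig <- pmax(sig0, 1e-9)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      dens <- vapply(seq_len(K),
                     function(k) f[k] * stats::dnorm(x, 0, sig[k]),
                     numeric(n))
      tot <- rowSums(dens)
      tot[tot <= 0] <- .Machine$double.xmin
      ll <- sum(log(tot))
      g <- dens / tot
      nk <- colSums(g)
      f <- nk / n
      sig <- sqrt(colSums(g * x2) / pmax(nk, 1e-300))
      sig <- pmax(sig, 1e-9)
      if (is.finite(ll) && abs(ll - ll_old) < tol * abs(ll)) {
        return(list(f = f, sig = sig, ll = ll, conv = TRUE))
      }
      ll_old <- ll
    }
    list(f = f, sig = sig, ll = ll_old, conv = FALSE)
  }
  # deterministic multi-start: quantile-spread seeds plus fixed jitters
  base <- s0 * exp(seq(-1.5, 1.5, length.out = K))
  jit <- c(1, 0.5, 2, 0.25, 4, 0.1, 8)
  best <- NULL
  for (s in seq_len(max(1L, n_starts))) {
    fit <- em(base * jit[(s - 1L) %% length(jit) + 1L])
    if (is.null(best) || fit$ll > best$ll) best <- fit
  }
  res <- .gauss_residuals(x, best$sig, best$f)
  fit <- .mixture_fit(K, best$f, best$sig, delta_t, "gaussian_em",
                      loglik = best$ll, converged = best$conv,
                      residuals = res)
  fit$bic <- -2 * best$ll + (2 * K - 1) * log(n)  # for manual K selection
  fit
}

# -- squared-displacement (jump-distance) mixture fitting --------------------

# parameter transform: theta = (logits of fractions [K-1], log of a [K])
# where a_i = 4 D_i dt + 4 s_loc^2 is the exponential mean of component i.
.theta_unpack <- function(theta, K) {
  if (K == 1L) return(list(f = 1, a = exp(theta)))
  z <- c(theta[seq_len(K - 1L)], 0)
  ez <- exp(z - max(z))
  list(f = ez / sum(ez), a = exp(theta[K:(2L * K - 1L)]))
}

# weighted squared CDF error at evaluation points u (empirical CDF values
# p, weights w). Weights 1/(F(1-F)) equalize the variance of the empirical
# CDF across its range, which markedly improves the efficiency of the
# deconvolution compared to unweighted least squares.
.sqd_objective <- function(theta, K, u, p, w) {
  par <- .theta_unpack(theta, K)
  m <- 1 - colSums(par$f * exp(-outer(1 / par$a, u)))
  sum(w * (m - p)^2)
}

# evaluation grid: all points for small samples, else evenly spaced order
# statistics (keeps the objective cheap and deterministic)
.cdf_grid <- function(r2, n_eval = 2000L) {
  u <- sort(r2)
  n <- length(u)
  if (n > n_eval) {
    idx <- unique(round(seq(1, n, length.out = n_eval)))
    p <- (idx - 0.5) / n
    u <- u[idx]
  } else {
    p <- (seq_len(n) - 0.5) / n
  }
  w <- 1 / pmax(p * (1 - p), 1e-4)
  list(u = u, p = p, w = w / sum(w))
}

.sqd_fit_once <- function(theta0, K, u, p, w) {
  fn <- function(theta) .sqd_objective(theta, K, u, p, w)
  if (length(theta0) == 1L) {
    stats::optim(theta0, fn, method = "Brent",
                 lower = theta0 - 25, upper = theta0 + 25,
                 control = list(maxit = 5000L))
  } else {
    stats::optim(theta0, fn, method = "Nelder-Mead",
                 control = list(maxit = 5000L, reltol = 1e-12))
  }
}

# deterministic multi-start seeds for log(a)
.sqd_starts <- function(r2, K, n_starts) {
  qs <- stats::quantile(r2[r2 > 0], probs = seq(0.15, 0.9, length.out = K),
                        names = FALSE)
  if (any(!is.finite(log(qs)))) qs <- rep(max(mean(r2), 1e-9), K)
  base <- log(sort(qs))
  scales <- list(0, 1, -1, c(-1.5, 1.5), 2)
  starts <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    sc <- scales[[(s - 1L) %% length(scales) + 1L]]
    starts[[s]] <- c(rep(0, K - 1L), base + rep_len(sc, K))
  }
  starts
}

#' Fit a multi-population jump-distance (squared-displacement) mixture
#'
#' Fits the mixture model for squared 2D jumps of K Brownian populations,
#' `P(r^2 <= u) = 1 - sum_i f_i exp(-u / (4 D_i delta_t + 4 sigma_loc^2))`,
#' by variance-weighted least squares on the empirical CDF (weights
#' `1/(F(1-F))`, which equalize the pointwise variance of the empirical CDF;
#' bin-independent). Residuals for
#' reporting are computed on the jump-distance probability histogram
#' (default 50 equal-width bins spanning [0, 99.5th percentile of r]), the
#' convention used for residual panels of jump-distance figures.
#'
#' @param r2 Numeric vector of squared displacements (um^2), as produced by
#'   [squared_displacements()].
#' @param K Number of diffusive populations (default 3: slow, intermediate,
#'   mobile).
#' @param delta_t Frame interval in seconds.
#' @param sigma_loc Known localization error per coordinate in um, added to
#'   each component's exponential mean as `4 sigma_loc^2`. Default 0 (no
#'   correction), in which case fitted D values absorb localization error.
#' @param n_starts Number of deterministic multi-start seeds.
#' @param n_bins Number of histogram bins for residual reporting.
#' @return A `mixture_fit` with components sorted by ascending D: fractions,
#'   D (um^2/s; clipped at 1e-6 with `d_clipped` flag if the
#'   localization-error correction would push a component negative), the
#'   histogram residual table and `max_abs_residual`.
#' @examples
#' r2 <- 4 * 0.1 * 0.03 * stats::rexp(2000)   # single population, D = 0.1
#' fit_sqd_mixture(r2, K = 1, delta_t = 0.03)
#' @export
fit_sqd_mixture <- function(r2, K = 3L, delta_t = 0.030, sigma_loc = 0,
                            n_starts = 5L, n_bins = 50L) {
  r2 <- r2[is.finite(r2) & r2 >= 0]
  if (length(r2) < 10L * K) stop("need at least 10*K squared displacements")
  grid <- .cdf_grid(r2)
  best <- NULL
  conv <- FALSE
  for (theta0 in .sqd_starts(r2, K, n_starts)) {
    opt <- .sqd_fit_once(theta0, K, grid$u, grid$p, grid$w)
    if (is.null(best) || opt$value < best$value) {
      best <- opt
      conv <- opt$convergence == 0L
    }
  }
  par <- .theta_unpack(best$par, K)
  ord <- order(par$a)
  a <- par$a[ord]; f <- par$f[ord]
  D_raw <- (a - 4 * sigma_loc^2) / (4 * delta_t)
  clipped <- any(D_raw < 1e-6)
  D <- pmax(D_raw, 1e-6)
  res <- .jump_residuals(sqrt(r2), a, f, n_bins = n_bins)
  .mixture_fit(K, f, sqrt(2 * D * delta_t), delta_t, "sqd_cdf_ls",
               sse = best$value, converged = conv,
               warning = if (conv) NA_character_ else "optimizer did not converge",
               residuals = res, D = D, d_clipped = clipped)
}

#' Globally fit jump-distance mixtures across conditions with shared D
#'
#' Joint least-squares fit over two or more conditions in which the K
#' diffusion coefficients are shared across conditions while the population
#' fractions are condition-specific — the "global diffusion constants"
#' convention that makes population sizes directly comparable between
#' conditions.
#'
#' @param r2_list Named list of squared-displacement vectors, one per
#'   condition (>= 2 conditions).
#' @param K Number of populations.
#' @param delta_t Frame interval in seconds.
#' @param sigma_loc Known localization error per coordinate (um); default 0.
#' @param n_starts Deterministic multi-start seeds.
#' @param n_bins Histogram bins for per-condition residuals.
#' @return A named list of `mixture_fit`, one per condition, sharing D.
#' @export
fit_sqd_global <- function(r2_list, K = 3L, delta_t = 0.030, sigma_loc = 0,
                           n_starts = 5L, n_bins = 50L) {
  if (!is.list(r2_list) || length(r2_list) < 2L)
    stop("global fit needs at least 2 conditions")
  C <- length(r2_list)
  if (is.null(names(r2_list))) names(r2_list) <- paste0("condition", seq_len(C))
  r2_list <- lapply(r2_list, function(v) v[is.finite(v) & v >= 0])
  for (v in r2_list) if (length(v) < 10L * K)
    stop("each condition needs at least 10*K squared displacements")
  grids <- lapply(r2_list, .cdf_grid)
  # theta = (per-condition logits [C x (K-1)], shared log a [K])
  obj <- function(theta) {
    la <- theta[(C * (K - 1L) + 1L):(C * (K - 1L) + K)]
    a <- exp(la)
    tot <- 0
    for (ci in seq_len(C)) {
      lo <- if (K > 1L) theta[((ci - 1L) * (K - 1L) + 1L):(ci * (K - 1L))] else numeric(0)
      z <- c(lo, 0); ez <- exp(z - max(z)); f <- ez / sum(ez)
      g <- grids[[ci]]
      m <- 1 - colSums(f * exp(-outer(1 / a, g$u)))
      tot <- tot + sum(g$w * (m - g$p)^2)
    }
    tot
  }
  pooled <- unlist(r2_list, use.names = FALSE)
  best <- NULL; conv <- FALSE
  for (st in .sqd_starts(pooled, K, n_starts)) {
    theta0 <- c(rep(0, C * (K - 1L)), st[K:(2L * K - 1L)])
    opt <- stats::optim(theta0, obj, method = "Nelder-Mead",
                        control = list(maxit = 10000L, reltol = 1e-12))
    if (is.null(best) || opt$value < best$value) {
      best <- opt; conv <- opt$convergence == 0L
    }
  }
  la <- best$par[(C * (K - 1L) + 1L):(C * (K - 1L) + K)]
  a <- exp(la)
  ord <- order(a); a <- a[ord]
  D_raw <- (a - 4 * sigma_loc^2) / (4 * delta_t)
  clipped <- any(D_raw < 1e-6)
  D <- pmax(D_raw, 1e-6)
  out <- vector("list", C)
  for (ci in seq_len(C)) {
    lo <- if (K > 1L) best$par[((ci - 1L) * (K - 1L) + 1L):(ci * (K - 1L))] else numeric(0)
    z <- c(lo, 0); ez <- exp(z - max(z)); f <- (ez / sum(ez))[ord]
    res <- .jump_residuals(sqrt(r2_list[[ci]]), a, f, n_bins = n_bins)
    out[[ci]] <- .mixture_fit(K, f, sqrt(2 * D * delta_t), delta_t,
                              "sqd_cdf_ls_global", sse = best$value,
                              converged = conv,
                              warning = if (conv) NA_character_
                                        else "optimizer did not converge",
                              residuals = res, D = D, d_clipped = clipped)
  }
  names(out) <- names(r2_list)
  out
}

# -- MSD ---------------------------------------------------------------------

#' Ensemble mean-squared displacement versus time lag
#'
#' For each lag k = 1..`max_lag_frames`, averages the squared 2D displacement
#' over every frame pair separated by exactly k frames, pooled over all
#' tracks (ensemble time-averaged MSD), with the standard error of the mean
#' over pairs.
#'
#' @param tracks A track table.
#' @param max_lag_frames Largest lag in frames (>= 1).
#' @param delta_t Frame interval in seconds (defaults to the table's
#'   `delta_t` attribute, else 0.030).
#' @return A data frame of class `msd_curve`: `lag_frames, lag_s, msd_um2,
#'   n_pairs, sem_um2`.
#' @export
msd <- function(tracks, max_lag_frames = 10L, delta_t = NULL) {
  stopifnot(max_lag_frames >= 1L)
  if (is.null(delta_t)) delta_t <- attr(tracks, "delta_t")
  if (is.null(delta_t)) delta_t <- 0.030
  per <- .split_tracks(tracks)
  sums <- numeric(max_lag_frames)
  sq <- numeric(max_lag_frames)
  cnt <- integer(max_lag_frames)
  for (d in per) {
    nf <- nrow(d)
    if (nf < 2) next
    for (k in seq_len(max_lag_frames)) {
      i <- match(d$frame + k, d$frame)
      ok <- which(!is.na(i))
      if (length(ok) == 0) next
      r2 <- (d$x_um[i[ok]] - d$x_um[ok])^2 + (d$y_um[i[ok]] - d$y_um[ok])^2
      sums[k] <- sums[k] + sum(r2)
      sq[k] <- sq[k] + sum(r2^2)
      cnt[k] <- cnt[k] + length(ok)
    }
  }
  m <- ifelse(cnt > 0, sums / cnt, NA_real_)
  v <- ifelse(cnt > 1, (sq - cnt * m^2) / (cnt - 1), NA_real_)
  out <- data.frame(lag_frames = seq_len(max_lag_frames),
                    lag_s = seq_len(max_lag_frames) * delta_t,
                    msd_um2 = m, n_pairs = cnt,
                    sem_um2 = sqrt(pmax(v, 0) / pmax(cnt, 1)))
  class(out) <- c("msd_curve", "data.frame")
  attr(out, "delta_t") <- delta_t
  out
}

#' Estimate D from the initial slope of an MSD curve
#'
#' Weighted linear fit `MSD(tau) = 4 D tau + b` over the first
#' `n_fit_points` lags (weights 1/SEM^2 where available). The offset b
#' absorbs localization error; a negative slope is truncated to D = 0 and
#' flagged. The fit's R^2 flags non-linear (e.g. ballistic or confined)
#' curves.
#'
#' @param curve An `msd_curve` from [msd()].
#' @param n_fit_points Number of initial lags used (>= 2).
#' @return A list: `D` (um^2/s), `offset` (um^2), `r_squared`, `clipped`.
#' @export
d_from_msd <- function(curve, n_fit_points = 4L) {
  stopifnot(n_fit_points >= 2L)
  if (nrow(curve) < n_fit_points)
    stop("MSD curve has fewer lags than n_fit_points")
  d <- curve[seq_len(n_fit_points), ]
  if (any(!is.finite(d$msd_um2))) stop("MSD curve has empty lags in fit range")
  w <- if (all(is.finite(d$sem_um2)) && all(d$sem_um2 > 0)) 1 / d$sem_um2^2
       else rep(1, n_fit_points)
  fit <- stats::lm(msd_um2 ~ lag_s, data = d, weights = w)
  slope <- unname(stats::coef(fit)[2])
  D <- slope / 4
  clipped <- D < 0
  r2fit <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn
  list(D = max(D, 0), offset = unname(stats::coef(fit)[1]),
       r_squared = r2fit, clipped = clipped)
}
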