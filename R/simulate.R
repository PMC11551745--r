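# Synthetic single-molecule microscopy (SMM) data generator: multi-population
# Brownian motion confined to spherocylindrical cells, with photobleaching,
# localization noise, and optionally molecules tethered near replisome foci.

# Run code with a locally seeded RNG, restoring global state afterwards.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-cell substream seed derived from the master seed.
.cell_seed <- function(seed, cell_idx) {
  (as.numeric(seed) * 48271 + cell_idx * 69621) %% 2147483587 + 1
}

#' Define a mixture of diffusive populations
#'
#' A mixture of `K` Brownian populations with occupancy fractions `f_i` and
#' diffusion coefficients `D_i`. Per-coordinate frame-to-frame steps of
#' population i are zero-mean Gaussian with standard deviation
#' `sigma_i = sqrt(2 * D_i * delta_t)`, so `D_i = sigma_i^2 / (2 * delta_t)`.
#' Components are stored sorted by ascending `D` (slow, intermediate, mobile).
#'
#' @param fractions Numeric vector of occupancy fractions, summing to 1.
#' @param D Diffusion coefficients in um^2/s, same length as `fractions`.
#' @param delta_t Frame interval in seconds.
#' @return An object of class `population_mixture` with elements `K`,
#'   `fractions`, `D`, `sigma` and `delta_t`.
#' @examples
#' population_mixture(c(1/3, 1/3, 1/3), c(0.023, 0.128, 0.6), 0.030)
#' @export
population_mixture <- function(fractions, D, delta_t) {
  stopifnot(length(fractions) == length(D), length(D) >= 1)
  if (any(fractions < 0) || any(D < 0)) stop("fractions and D must be >= 0")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (delta_t <= 0) stop("delta_t must be > 0")
  ord <- order(D)
  structure(list(K = length(D), fractions = fractions[ord], D = D[ord],
                 sigma = sqrt(2 * D[ord] * delta_t), delta_t = delta_t),
            class = "population_mixture")
}

#' @export
print.population_mixture <- function(x, ...) {
  cat(sprintf("population_mixture with %d components (delta_t = %g s):\n", x$K, x$delta_t))
  for (i in seq_len(x$K))
    cat(sprintf("  f = %.3f, D = %.4g um^2/s, sigma = %.4g um\n",
                x$fractions[i], x$D[i], x$sigma[i]))
  invisible(x)
}

#' Build a simulation configuration
#'
#' Collects every knob of the SMM simulator. Defaults mirror a slimfield
#' acquisition of a rod-shaped bacterium: 30 ms frames, cells about
#' 1 x 2.5 um, localization error of 30 nm, an initial photobleaching phase
#' after which only a handful of emitters per cell remain, and tracks kept
#' only if they carry at least five frame-to-frame steps.
#'
#' @param mixture A [population_mixture()]: the generative truth.
#' @param delta_t Frame interval in seconds (default 0.030).
#' @param n_frames Number of recorded (post-bleaching) frames; must be >= 6.
#' @param n_cells Number of cells to simulate.
#' @param n_molecules Fluorophores per cell at the start of the bleaching
#'   phase.
#' @param loc_noise_sigma Isotropic localization error in um added to every
#'   reported position.
#' @param survival_prob Per-frame probability that a molecule remains
#'   emissive (photobleaching is molecule-level disappearance).
#' @param bleach_phase_frames Number of discarded pre-bleaching frames; the
#'   same per-frame survival applies during this phase, thinning the initial
#'   population down to single-molecule density.
#' @param n_foci Replisome (DnaX) foci per cell.
#' @param anchor_fraction Fraction of slow-population molecules tethered
#'   within `anchor_radius` of a focus.
#' @param anchor_radius Tether radius in um.
#' @param polar_bias Probability that a focus is placed in a polar cap
#'   rather than uniformly in the cell (0 = uniform).
#' @param geometry Template [cell_geometry()]; per-cell sizes are jittered by
#'   `cell_jitter` and cells are laid out side by side with random
#'   orientations.
#' @param cell_jitter Relative cell-to-cell size variability.
#' @param min_steps Minimum number of adjacent-frame steps for an emitted
#'   track.
#' @param channel Channel label written to the track table (e.g. "green" for
#'   crRNP-mNeonGreen, "red" for DnaX-mScarlet).
#' @param condition Free-text condition label.
#' @param seed Master seed; per-cell substreams are derived from it, so the
#'   same config yields bit-identical output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(mixture = population_mixture(c(0.34, 0.36, 0.30),
                                                    c(0.023, 0.128, 0.6), 0.030),
                       delta_t = 0.030,
                       n_frames = 400L,
                       n_cells = 25L,
                       n_molecules = 80L,
                       loc_noise_sigma = 0.03,
                       survival_prob = 0.98,
                       bleach_phase_frames = 100L,
                       n_foci = 0L,
                       anchor_fraction = 0,
                       anchor_radius = 0.15,
                       polar_bias = 0,
                       geometry = cell_geometry(2.5, 0.5),
                       cell_jitter = 0.1,
                       min_steps = 5L,
                       channel = "green",
                       condition = "custom",
                       seed = 1L) {
  cfg <- structure(list(mixture = mixture, delta_t = delta_t,
                        n_frames = as.integer(n_frames),
                        n_cells = as.integer(n_cells),
                        n_molecules = as.integer(n_molecules),
                        loc_noise_sigma = loc_noise_sigma,
                        survival_prob = survival_prob,
                        bleach_phase_frames = as.integer(bleach_phase_frames),
                        n_foci = as.integer(n_foci),
                        anchor_fraction = anchor_fraction,
                        anchor_radius = anchor_radius,
                        polar_bias = polar_bias,
                        geometry = geometry, cell_jitter = cell_jitter,
                        min_steps = as.integer(min_steps),
                        channel = channel, condition = condition,
                        seed = as.integer(seed)),
                   class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param config A `sim_config`.
#' @return The config, invisibly; errors describe the first violated
#'   constraint.
#' @export
validate_sim_config <- function(config) {
  if (!inherits(config, "sim_config")) stop("not a sim_config")
  if (!inherits(config$mixture, "population_mixture"))
    stop("mixture must be a population_mixture")
  if (config$delta_t <= 0) stop("delta_t must be > 0")
  if (config$n_frames < 6L) stop("n_frames must be >= 6")
  if (config$survival_prob < 0 || config$survival_prob > 1)
    stop("survival_prob must be in [0, 1]")
  if (config$anchor_fraction < 0 || config$anchor_fraction > 1)
    stop("anchor_fraction must be in [0, 1]")
  if (config$anchor_fraction > 0 && config$n_foci == 0L)
    stop("anchor_fraction > 0 requires n_foci > 0")
  if (config$anchor_fraction > 0 &&
      config$anchor_radius >= config$geometry$radius)
    stop("anchor_radius must be smaller than the cell radius")
  if (config$loc_noise_sigma < 0) stop("loc_noise_sigma must be >= 0")
  if (abs(config$mixture$delta_t - config$delta_t) > 1e-12)
    stop("mixture delta_t must match config delta_t")
  invisible(config)
}

#' Preset simulation configurations for the studied conditions
#'
#' Named presets describing the experimental conditions of the Type IV-A1
#' crRNP / DnaX tracking study: a wild-type strain, a strain with a
#' non-targeted high-copy plasmid, genome targeting, plasmid targeting, and
#' DnaX-mScarlet imaging with and without a targeted plasmid. Slow and
#' intermediate diffusion coefficients are 0.023 and 0.128 um^2/s; the mobile
#' coefficient (0.6 um^2/s) and per-condition fractions are package defaults
#' chosen to reproduce the qualitative population shifts between conditions.
#'
#' @param name One of `"wildtype"`, `"high_copy_plasmid"`, `"genome_target"`,
#'   `"nontarget_plasmid"`, `"target_plasmid"`, `"dnax_nontarget"`,
#'   `"dnax_target"`.
#' @param seed Master seed stored in the config.
#' @return A `sim_config`.
#' @examples
#' cfg <- sim_preset("wildtype")
#' cfg$delta_t            # 0.030 s
#' cfg$mixture$K          # 3 populations
#' @export
sim_preset <- function(name, seed = 1L) {
  dt <- 0.030
  crD <- c(0.023, 0.128, 0.6)
  dnD <- c(0.020, 0.120, 0.5)
  cfg <- switch(
    name,
    wildtype = sim_config(
      mixture = population_mixture(c(0.34, 0.36, 0.30), crD, dt),
      condition = "wildtype", seed = seed),
    high_copy_plasmid = sim_config(
      mixture = population_mixture(c(0.15, 0.55, 0.30), crD, dt),
      condition = "high_copy_plasmid", seed = seed),
    genome_target = sim_config(
      mixture = population_mixture(c(0.45, 0.35, 0.20), crD, dt),
      condition = "genome_target", seed = seed),
    nontarget_plasmid = sim_config(
      mixture = population_mixture(c(0.20, 0.50, 0.30), crD, dt),
      n_foci = 3L, anchor_fraction = 0.05,
      condition = "nontarget_plasmid", seed = seed),
    target_plasmid = sim_config(
      mixture = population_mixture(c(0.55, 0.30, 0.15), crD, dt),
      n_foci = 3L, anchor_fraction = 0.5, polar_bias = 0.6,
      condition = "target_plasmid", seed = seed),
    dnax_nontarget = sim_config(
      mixture = population_mixture(c(0.20, 0.30, 0.50), dnD, dt),
      n_foci = 3L, anchor_fraction = 0.8, channel = "red",
      condition = "dnax_nontarget", seed = seed),
    dnax_target = sim_config(
      mixture = population_mixture(c(0.50, 0.35, 0.15), dnD, dt),
      n_foci = 3L, anchor_fraction = 0.8, channel = "red",
      condition = "dnax_target", seed = seed),
    stop("unknown preset: ", name)
  )
  cfg
}

# Per-cell jittered geometry laid out along a row in the lab frame.
.cell_geometries <- function(config) {
  g <- config$geometry
  out <- vector("list", config$n_cells)
  for (i in seq_len(config$n_cells)) {
    .with_seed(.cell_seed(config$seed, i) + 7L, {
      jl <- 1 + stats::runif(1, -config$cell_jitter, config$cell_jitter)
      jr <- 1 + stats::runif(1, -config$cell_jitter / 2, config$cell_jitter / 2)
      len <- max(g$length * jl, 2 * g$radius * jr + 1e-6)
      theta <- stats::runif(1, 0, pi)
      out[[i]] <- cell_geometry(len, g$radius * jr,
                                cx = (i - 1) * (2 * g$length),
                                cy = 0, theta = theta)
    })
  }
  out
}

# Sample n focus positions in a cell; with probability polar_bias a focus is
# placed in a polar cap (|x_cell| > h) rather than uniformly.
.sim_foci_in_cell <- function(geom, n, polar_bias) {
  if (n == 0L) return(data.frame(focus_id = integer(0), x_um = numeric(0),
                                 y_um = numeric(0)))
  h <- geom$length / 2 - geom$radius
  polar <- stats::runif(n) < polar_bias
  xs <- numeric(n); ys <- numeric(n)
  # rejection sampling per focus keeps the draw order deterministic
  for (i in seq_len(n)) {
    repeat {
      p <- .runif_in_cell(geom, 1L)
      cf <- to_cell_frame(geom, p$x, p$y)
      if (!polar[i] || abs(cf$x) > h * 0.75) {
        xs[i] <- p$x; ys[i] <- p$y
        break
      }
    }
  }
  data.frame(focus_id = seq_len(n), x_um = xs, y_um = ys)
}

#' Simulate replisome focus positions
#'
#' Draws `n_foci` focus positions per cell, uniformly inside the cell or
#' biased toward the polar caps (`polar_bias` > 0), emulating the greater
#' likelihood of encountering replicating high-copy plasmids near the poles.
#'
#' @param config A `sim_config`.
#' @return A data frame `cell_id, focus_id, x_um, y_um` (a focus set).
#' @export
simulate_foci <- function(config) {
  validate_sim_config(config)
  geoms <- .cell_geometries(config)
  out <- vector("list", config$n_cells)
  for (i in seq_len(config$n_cells)) {
    out[[i]] <- .with_seed(.cell_seed(config$seed, i) + 13L, {
      f <- .sim_foci_in_cell(geoms[[i]], config$n_foci, config$polar_bias)
      if (nrow(f)) cbind(cell_id = i, f)
      else data.frame(cell_id = integer(0), focus_id = integer(0),
                      x_um = numeric(0), y_um = numeric(0))
    })
  }
  do.call(rbind, out)
}

# Simulate one cell's molecules. Molecules alive at the end of the bleaching
# phase start from the stationary (uniform) position distribution, which is
# exact for non-interacting reflected Brownian motion, so the bleaching
# phase itself needs no trajectory integration.
.sim_cell <- function(config, geom, cell_id, foci) {
  mix <- config$mixture
  nm <- config$n_molecules
  nf <- config$n_frames
  comp <- sample.int(mix$K, nm, replace = TRUE, prob = mix$fractions)
  p_bleach <- config$survival_prob^config$bleach_phase_frames
  alive0 <- stats::runif(nm) < p_bleach
  anchored <- rep(FALSE, nm)
  focus_of <- rep(NA_integer_, nm)
  if (config$anchor_fraction > 0 && nrow(foci) > 0) {
    slow <- comp == 1L
    anchored <- slow & stats::runif(nm) < config$anchor_fraction
    focus_of[anchored] <- sample.int(nrow(foci), sum(anchored), replace = TRUE)
  }
  idx <- which(alive0)
  n <- length(idx)
  if (n == 0L)
    return(list(tracks = NULL,
                truth = data.frame(cell_id = integer(0), track_id = integer(0),
                                   component = integer(0), anchored = logical(0),
                                   focus_id = integer(0))))
  # observed frames per molecule: 1 + geometric number of survivals
  frames_alive <- if (config$survival_prob >= 1) rep(nf, n)
    else pmin(1L + stats::rgeom(n, 1 - config$survival_prob), nf)
  # initial positions: stationary distribution (uniform; anchored -> disc)
  X <- matrix(NA_real_, nrow = nf, ncol = n)
  Y <- matrix(NA_real_, nrow = nf, ncol = n)
  init <- .runif_in_cell(geom, n)
  x <- init$x; y <- init$y
  anc <- anchored[idx]
  if (any(anc)) {
    k <- which(anc)
    fid <- focus_of[idx][k]
    rr <- config$anchor_radius * sqrt(stats::runif(length(k)))
    aa <- stats::runif(length(k), 0, 2 * pi)
    x[k] <- foci$x_um[fid] + rr * cos(aa)
    y[k] <- foci$y_um[fid] + rr * sin(aa)
    p <- reflect_into_cell(geom, x[k], y[k])
    x[k] <- p$x; y[k] <- p$y
  }
  X[1, ] <- x; Y[1, ] <- y
  sig <- mix$sigma[comp[idx]]
  dxs <- matrix(stats::rnorm((nf - 1) * n, 0, sig), nrow = nf - 1, byrow = TRUE)
  dys <- matrix(stats::rnorm((nf - 1) * n, 0, sig), nrow = nf - 1, byrow = TRUE)
  for (t in seq_len(nf - 1)) {
    x <- x + dxs[t, ]; y <- y + dys[t, ]
    if (any(anc)) {
      k <- which(anc)
      fid <- focus_of[idx][k]
      p <- .reflect_into_disc(foci$x_um[fid], foci$y_um[fid],
                              config$anchor_radius, x[k], y[k])
      x[k] <- p$x; y[k] <- p$y
    }
    p <- reflect_into_cell(geom, x, y)
    x <- p$x; y <- p$y
    X[t + 1, ] <- x; Y[t + 1, ] <- y
  }
  keep <- frames_alive >= config$min_steps + 1L
  if (!any(keep))
    return(list(tracks = NULL,
                truth = data.frame(cell_id = integer(0), track_id = integer(0),
                                   component = integer(0), anchored = logical(0),
                                   focus_id = integer(0))))
  rows <- vector("list", sum(keep))
  ki <- which(keep)
  for (j in seq_along(ki)) {
    m <- ki[j]
    fr <- seq_len(frames_alive[m])
    rows[[j]] <- data.frame(cell_id = cell_id, track_id = idx[m],
                            channel = config$channel, frame = fr - 1L,
                            x_um = X[fr, m], y_um = Y[fr, m])
  }
  tracks <- do.call(rbind, rows)
  if (config$loc_noise_sigma > 0) {
    tracks$x_um <- tracks$x_um + stats::rnorm(nrow(tracks), 0, config$loc_noise_sigma)
    tracks$y_um <- tracks$y_um + stats::rnorm(nrow(tracks), 0, config$loc_noise_sigma)
  }
  truth <- data.frame(cell_id = cell_id, track_id = idx[keep],
                      component = comp[idx][keep],
                      anchored = anchored[idx][keep],
                      focus_id = focus_of[idx][keep])
  list(tracks = tracks, truth = truth)
}

#' Simulate single-molecule tracks with known ground truth
#'
#' Each molecule is assigned one mixture component by its fraction and
#' performs reflected Brownian motion inside its cell; per frame each
#' coordinate advances by a zero-mean Gaussian step of standard deviation
#' `sqrt(2 * D_i * delta_t)`. Tethered molecules diffuse identically but are
#' additionally confined within `anchor_radius` of their focus. Molecules
#' photobleach with probability `1 - survival_prob` per frame (also through
#' the discarded pre-bleaching phase); reported positions carry isotropic
#' Gaussian localization noise. Only tracks with at least `min_steps`
#' adjacent-frame steps are emitted. All randomness derives from
#' `config$seed` via per-cell substreams, so identical configs give
#' bit-identical output.
#'
#' @param config A `sim_config`.
#' @return A list with elements:
#' \describe{
#'   \item{tracks}{data frame `cell_id, track_id, channel, frame, x_um, y_um`}
#'   \item{truth}{data frame per emitted track: `cell_id, track_id,
#'     component, anchored, focus_id`}
#'   \item{foci}{data frame `cell_id, focus_id, x_um, y_um`}
#'   \item{geometries}{data frame `cell_id, length_um, radius_um, cx_um,
#'     cy_um, theta_rad`}
#'   \item{config}{the config used}
#' }
#' @examples
#' sim <- simulate_tracks(sim_config(n_cells = 2, n_frames = 50, seed = 7))
#' head(sim$tracks)
#' @export
simulate_tracks <- function(config) {
  validate_sim_config(config)
  geoms <- .cell_geometries(config)
  foci <- simulate_foci(config)
  track_l <- vector("list", config$n_cells)
  truth_l <- vector("list", config$n_cells)
  for (i in seq_len(config$n_cells)) {
    fi <- foci[foci$cell_id == i, , drop = FALSE]
    res <- .with_seed(.cell_seed(config$seed, i),
                      .sim_cell(config, geoms[[i]], i, fi))
    track_l[[i]] <- res$tracks
    truth_l[[i]] <- res$truth
  }
  tracks <- do.call(rbind, track_l[!vapply(track_l, is.null, logical(1))])
  if (is.null(tracks))
    tracks <- data.frame(cell_id = integer(0), track_id = integer(0),
                         channel = character(0), frame = integer(0),
                         x_um = numeric(0), y_um = numeric(0))
  rownames(tracks) <- NULL
  truth <- do.call(rbind, truth_l)
  rownames(truth) <- NULL
  geom_df <- data.frame(
    cell_id = seq_len(config$n_cells),
    length_um = vapply(geoms, `[[`, numeric(1), "length"),
    radius_um = vapply(geoms, `[[`, numeric(1), "radius"),
    cx_um = vapply(geoms, `[[`, numeric(1), "cx"),
    cy_um = vapply(geoms, `[[`, numeric(1), "cy"),
    theta_rad = vapply(geoms, `[[`, numeric(1), "theta"))
  list(tracks = tracks, truth = truth, foci = foci, geometries = geom_df,
       config = config)
}
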