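# shared fixtures: all synthetic, generated in code at test time

quiet <- function(expr) suppressMessages(expr)

# draw n squared 2D jumps directly from a K-component Brownian mixture
sample_mixture_r2 <- function(n, fractions, D, delta_t, seed,
                              sigma_loc = 0) {
  set.seed(seed)
  a <- 4 * D * delta_t + 4 * sigma_loc^2
  comp <- sample(length(D), n, replace = TRUE, prob = fractions)
  stats::rexp(n, rate = 1 / a[comp])
}

# config for effectively unconfined motion: huge cell, no bleaching phase
unconfined_config <- function(D, n_molecules = 200L, n_frames = 60L,
                              loc_noise_sigma = 0, seed = 1L,
                              survival_prob = 1, fractions = NULL,
                              n_cells = 1L) {
  if (is.null(fractions)) fractions <- rep(1 / length(D), length(D))
  sim_config(mixture = population_mixture(fractions, D, 0.030),
             geometry = cell_geometry(60, 15), cell_jitter = 0,
             n_cells = n_cells, n_molecules = n_molecules,
             n_frames = n_frames, loc_noise_sigma = loc_noise_sigma,
             survival_prob = survival_prob, bleach_phase_frames = 0L,
             seed = seed)
}

# tiny deterministic track table builder
make_track <- function(x, y, cell_id = 1L, track_id = 1L,
                       channel = "green", frame = seq_along(x) - 1L) {
  data.frame(cell_id = cell_id, track_id = track_id, channel = channel,
             frame = frame, x_um = x, y_um = y)
}
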