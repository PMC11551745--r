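test_that("immobile noiseless molecules give constant tracks", {
  cfg <- sim_config(mixture = population_mixture(1, 0, 0.030),
                    n_cells = 2L, n_molecules = 20L, n_frames = 30L,
                    loc_noise_sigma = 0, survival_prob = 1,
                    bleach_phase_frames = 0L, seed = 4)
  sim <- simulate_tracks(cfg)
  d <- quiet(frame_displacements(sim$tracks))
  expect_true(all(d == 0))
})

test_that("mixture second moment matches the closed-form mean squared jump", {
  # closed form: E[r^2] = 4 (sum_i f_i D_i) dt + 4 s_loc^2, checked against
  # brute-force averaging over simulated steps
  f <- c(1/3, 2/3); D <- c(0.023, 0.128); dt <- 0.030
  cfg <- unconfined_config(D, fractions = f, n_molecules = 250L,
                           n_frames = 50L, seed = 8)
  sim <- simulate_tracks(cfg)
  r2 <- squared_displacements(sim$tracks)
  expect_gt(length(r2), 10000)
  expected <- 4 * sum(f * D) * dt
  se <- stats::sd(r2) / sqrt(length(r2))
  expect_lt(abs(mean(r2) - expected), 6 * se)
})

test_that("no bleaching and no boundary contact yields full-length tracks", {
  cfg <- unconfined_config(0.05, n_molecules = 30L, n_frames = 100L, seed = 5)
  sim <- simulate_tracks(cfg)
  steps <- tapply(sim$tracks$frame, sim$tracks$track_id, length) - 1L
  expect_true(all(steps == 99L))
})

test_that("identical configs give bit-identical output", {
  cfg <- sim_preset("target_plasmid", seed = 21)
  cfg$n_cells <- 4L
  s1 <- simulate_tracks(cfg)
  s2 <- simulate_tracks(cfg)
  expect_identical(s1$tracks, s2$tracks)
  expect_identical(s1$foci, s2$foci)
  expect_identical(s1$truth, s2$truth)
})

test_that("noiseless positions are confined to the cell", {
  cfg <- sim_config(mixture = population_mixture(1, 0.6, 0.030),
                    n_cells = 3L, n_molecules = 40L, n_frames = 80L,
                    loc_noise_sigma = 0, survival_prob = 1,
                    bleach_phase_frames = 0L, seed = 6)
  sim <- simulate_tracks(cfg)
  for (i in seq_len(nrow(sim$geometries))) {
    g <- cell_geometry(sim$geometries$length_um[i], sim$geometries$radius_um[i],
                       sim$geometries$cx_um[i], sim$geometries$cy_um[i],
                       sim$geometries$theta_rad[i])
    tt <- sim$tracks[sim$tracks$cell_id == i, ]
    expect_true(all(in_cell(g, tt$x_um, tt$y_um, tol = 1e-9)))
  }
})

test_that("1D steps follow the analytic Gaussian for unconfined motion", {
  # variance oracle: 2 D dt + 2 s_loc^2
  D <- 0.128; dt <- 0.030; sl <- 0.025
  cfg <- unconfined_config(D, n_molecules = 250L, n_frames = 50L,
                           loc_noise_sigma = sl, seed = 9)
  sim <- simulate_tracks(cfg)
  d <- quiet(frame_displacements(sim$tracks))
  expect_gt(length(d), 2e4)
  ks <- stats::ks.test(d, "pnorm", 0, sqrt(2 * D * dt + 2 * sl^2))
  expect_gt(ks$p.value, 0.01)
})

test_that("track lengths are geometric before the minimum-step filter", {
  p <- 0.9
  cfg <- unconfined_config(0.05, n_molecules = 600L, n_frames = 150L,
                           survival_prob = p, seed = 10)
  cfg$min_steps <- 1L
  sim <- simulate_tracks(cfg)
  len <- as.integer(tapply(sim$tracks$frame, sim$tracks$track_id, length))
  # P(len = k) = p^(k-1) (1-p) truncated at n_frames; the simulator only
  # emits tracks with >= min_steps + 1 = 2 frames, so condition on len >= 2:
  # P(len = k | len >= 2) = p^(k-2) (1-p), CDF 1 - p^(k-1)
  expect_true(all(len >= 2))
  ks <- unique(c(2:15, 20, 30, 150))
  obs <- table(cut(len, c(1, ks)))
  pr <- diff(c(0, 1 - p^(ks[-length(ks)] - 1), 1))
  chi <- suppressWarnings(stats::chisq.test(as.vector(obs), p = pr))
  expect_gt(chi$p.value, 0.01)
})

test_that("focus simulation is deterministic and supports polar bias", {
  cfg0 <- sim_config(n_foci = 0L, seed = 3)
  expect_equal(nrow(simulate_foci(cfg0)), 0L)
  cfg2 <- sim_config(n_foci = 2L, n_cells = 3L, seed = 3)
  expect_identical(simulate_foci(cfg2), simulate_foci(cfg2))
  # Monte-Carlo contrast: polar preset pushes foci toward the caps
  mean_axial <- function(polar_bias) {
    cfg <- sim_config(n_foci = 10L, n_cells = 100L, polar_bias = polar_bias,
                      cell_jitter = 0, seed = 12)
    fo <- simulate_foci(cfg)
    ge <- trackmix:::.cell_geometries(cfg)
    u <- numeric(0)
    for (i in seq_along(ge)) {
      fi <- fo[fo$cell_id == i, ]
      cf <- to_cell_frame(ge[[i]], fi$x_um, fi$y_um)
      u <- c(u, abs(cf$x) / ge[[i]]$length)
    }
    mean(u)
  }
  expect_gt(mean_axial(0.8), mean_axial(0))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_frames = 5L), "n_frames")
  expect_error(sim_config(anchor_fraction = 0.5, n_foci = 0L), "n_foci")
  expect_error(sim_config(anchor_fraction = 0.5, n_foci = 2L,
                          anchor_radius = 0.6,
                          geometry = cell_geometry(2.5, 0.5)),
               "anchor_radius")
  expect_error(sim_config(survival_prob = 1.2), "survival_prob")
})

test_that("presets carry the acquisition parameters and sum to one", {
  wt <- sim_preset("wildtype")
  expect_equal(wt$delta_t, 0.030)
  expect_equal(wt$mixture$K, 3L)
  expect_equal(wt$mixture$D[1:2], c(0.023, 0.128))
  for (nm in c("wildtype", "high_copy_plasmid", "genome_target",
               "nontarget_plasmid", "target_plasmid", "dnax_nontarget",
               "dnax_target")) {
    expect_equal(sum(sim_preset(nm)$mixture$fractions), 1, tolerance = 1e-12)
  }
  expect_gt(sim_preset("target_plasmid")$mixture$fractions[1],
            sim_preset("nontarget_plasmid")$mixture$fractions[1])
  expect_error(sim_preset("nope"), "unknown preset")
})

test_that("anchored molecules stay near their focus", {
  cfg <- sim_config(mixture = population_mixture(1, 0.023, 0.030),
                    n_cells = 2L, n_molecules = 30L, n_frames = 60L,
                    n_foci = 2L, anchor_fraction = 1, anchor_radius = 0.1,
                    loc_noise_sigma = 0, survival_prob = 1,
                    bleach_phase_frames = 0L, seed = 14)
  sim <- simulate_tracks(cfg)
  anch <- sim$truth[sim$truth$anchored, ]
  expect_gt(nrow(anch), 0)
  for (j in seq_len(nrow(anch))) {
    tt <- sim$tracks[sim$tracks$cell_id == anch$cell_id[j] &
                     sim$tracks$track_id == anch$track_id[j], ]
    fo <- sim$foci[sim$foci$cell_id == anch$cell_id[j] &
                   sim$foci$focus_id == anch$focus_id[j], ]
    d <- sqrt((tt$x_um - fo$x_um)^2 + (tt$y_um - fo$y_um)^2)
    expect_true(all(d <= cfg$anchor_radius + 1e-9))
  }
})
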