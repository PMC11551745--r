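test_that("standardization maps centre and poles to canonical coordinates", {
  g <- cell_geometry(2.5, 0.5, cx = 1.7, cy = -0.4, theta = 0.8)
  centre <- standardize(data.frame(x_um = 1.7, y_um = -0.4), g)
  expect_equal(unlist(centre), c(u = 0, v = 0), tolerance = 1e-12)
  pole <- from_cell_frame(g, 1.25, 0)
  p <- standardize(data.frame(x_um = pole$x, y_um = pole$y), g)
  expect_equal(p$u, 0.5, tolerance = 1e-12)
  expect_equal(p$v, 0, tolerance = 1e-12)
  wall <- from_cell_frame(g, 0, 0.5)
  w <- standardize(data.frame(x_um = wall$x, y_um = wall$y), g)
  expect_equal(w$v, 0.5, tolerance = 1e-12)
})

test_that("standardization is equivariant under rigid motion and drops outliers", {
  g1 <- cell_geometry(3, 0.4, theta = 0)
  set.seed(61)
  p <- trackmix:::.runif_in_cell(g1, 200L)
  s1 <- standardize(data.frame(x_um = p$x, y_um = p$y), g1)
  phi <- 1.2; tx <- 5; ty <- -2
  g2 <- cell_geometry(3, 0.4, cx = tx, cy = ty, theta = phi)
  s2 <- standardize(data.frame(x_um = tx + cos(phi) * p$x - sin(phi) * p$y,
                               y_um = ty + sin(phi) * p$x + cos(phi) * p$y),
                    g2)
  expect_equal(s2$u, s1$u, tolerance = 1e-9)
  expect_equal(s2$v, s1$v, tolerance = 1e-9)
  expect_message(
    out <- standardize(data.frame(x_um = c(0, 10), y_um = c(0, 10)), g1),
    "dropped 1")
  expect_equal(nrow(out), 1L)
})

test_that("density maps normalize to one and concentrate where tracks dwell", {
  g <- data.frame(cell_id = 1L, length_um = 2.5, radius_um = 0.5,
                  cx_um = 0, cy_um = 0, theta_rad = 0)
  centre <- make_track(x = rep(0, 30), y = rep(0, 30))
  m <- density_map(centre, g, grid_shape = c(21L, 11L))
  expect_equal(sum(m$density), 1, tolerance = 1e-12)
  ui <- 9:13; vi <- 4:8   # central block of the smoothed map
  expect_gt(sum(m$density[ui, vi]), 0.9)
  # uniform scanning: left and right halves carry similar mass
  cfg <- sim_config(mixture = population_mixture(1, 0.6, 0.030),
                    n_cells = 6L, n_molecules = 60L, n_frames = 100L,
                    survival_prob = 1, bleach_phase_frames = 0L,
                    loc_noise_sigma = 0, seed = 62)
  sim <- simulate_tracks(cfg)
  mu <- density_map(sim$tracks, sim$geometries, grid_shape = c(20L, 10L))
  left <- sum(mu$density[1:10, ]); right <- sum(mu$density[11:20, ])
  expect_lt(abs(left - right), 0.06)
  expect_true(all(mu$density >= 0))
})

test_that("polar anchoring shifts density mass toward the poles", {
  polar_mass <- function(preset) {
    cfg <- sim_preset(preset, seed = 63)
    cfg$n_cells <- 8L
    sim <- simulate_tracks(cfg)
    m <- density_map(sim$tracks, sim$geometries, grid_shape = c(20L, 10L))
    sum(m$density[c(1:4, 17:20), ])
  }
  expect_gt(polar_mass("target_plasmid"), polar_mass("wildtype"))
})

test_that("dwelling classification separates bound from diffusing molecules", {
  stat <- make_track(x = rep(1, 10), y = rep(1, 10))
  expect_equal(classify_dwelling(stat)$label, "static")
  run <- make_track(x = seq(0, by = 0.9 * 10 / 9, length.out = 10),
                    y = rep(0, 10))
  expect_equal(classify_dwelling(run)$label, "mobile")
  # simulated anchored (bound) vs mobile populations, >= 90% agreement
  cfg <- sim_config(mixture = population_mixture(c(0.5, 0.5), c(0.003, 0.6),
                                                 0.030),
                    n_cells = 6L, n_molecules = 40L, n_frames = 40L,
                    n_foci = 3L, anchor_fraction = 1, anchor_radius = 0.06,
                    loc_noise_sigma = 0.02, survival_prob = 0.985,
                    bleach_phase_frames = 0L, seed = 64)
  sim <- simulate_tracks(cfg)
  lab <- classify_dwelling(sim$tracks)
  key <- paste(lab$cell_id, lab$track_id)
  tkey <- paste(sim$truth$cell_id, sim$truth$track_id)
  truth_static <- sim$truth$component[match(key, tkey)] == 1L
  agree <- mean((lab$label == "static") == truth_static)
  expect_gte(agree, 0.9)
})

test_that("foci emerge from dwelling-track centroids with merging", {
  one <- make_track(x = rnorm(10, 1, 0.01), y = rnorm(10, 2, 0.01))
  f1 <- foci_from_dwelling(one)
  expect_equal(nrow(f1), 1L)
  expect_equal(f1$x_um, mean(one$x_um), tolerance = 1e-9)
  two <- rbind(make_track(x = rep(1, 8), y = rep(1, 8), track_id = 1L),
               make_track(x = rep(2, 8), y = rep(1, 8), track_id = 2L))
  expect_equal(nrow(foci_from_dwelling(two)), 2L)
  close_pair <- rbind(make_track(x = rep(1, 8), y = rep(1, 8), track_id = 1L),
                      make_track(x = rep(1.05, 8), y = rep(1, 8),
                                 track_id = 2L))
  merged <- foci_from_dwelling(close_pair)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$x_um, 1.025, tolerance = 1e-9)
  expect_equal(nrow(foci_from_dwelling(one[0, ])), 0L)
  # recovery on simulated anchored tracks: foci within 0.1 um of truth
  cfg <- sim_config(mixture = population_mixture(1, 0.002, 0.030),
                    n_cells = 3L, n_molecules = 30L, n_frames = 50L,
                    n_foci = 2L, anchor_fraction = 1, anchor_radius = 0.05,
                    loc_noise_sigma = 0.015, survival_prob = 1,
                    bleach_phase_frames = 0L, seed = 65)
  sim <- simulate_tracks(cfg)
  est <- foci_from_dwelling(sim$tracks, merge_radius = 0.2)
  for (i in seq_len(nrow(sim$foci))) {
    cand <- est[est$cell_id == sim$foci$cell_id[i], ]
    if (nrow(cand) == 0) next
    d <- sqrt((cand$x_um - sim$foci$x_um[i])^2 +
              (cand$y_um - sim$foci$y_um[i])^2)
    expect_lt(min(d), 0.1)
  }
})

test_that("nearest-focus distances match hand examples and the brute force", {
  tr <- make_track(x = rep(3, 6), y = rep(4, 6))
  fo <- data.frame(cell_id = 1L, focus_id = 1L, x_um = 0, y_um = 0)
  d <- nearest_focus_distances(tr, fo)
  expect_equal(d$distance_um, rep(5, 5))
  fo0 <- data.frame(cell_id = 1L, focus_id = 1L, x_um = 3, y_um = 4)
  expect_equal(nearest_focus_distances(tr, fo0)$distance_um, rep(0, 5))
  # randomized instances against an exhaustive all-pairs oracle
  set.seed(66)
  for (rep in 1:5) {
    n_tracks <- sample(2:4, 1)
    tr <- do.call(rbind, lapply(seq_len(n_tracks), function(i)
      make_track(x = runif(7), y = runif(7), track_id = i,
                 cell_id = sample(1:2, 1))))
    fo <- data.frame(cell_id = sample(1:2, 12, replace = TRUE),
                     focus_id = 1:12, x_um = runif(12), y_um = runif(12))
    got <- quiet(nearest_focus_distances(tr, fo, points_per_track = 5))
    for (r in seq_len(nrow(got))) {
      tt <- tr[tr$cell_id == got$cell_id[r] & tr$track_id == got$track_id[r], ]
      tt <- tt[order(tt$frame), ][got$point_index[r], ]
      ff <- fo[fo$cell_id == got$cell_id[r], ]
      brute <- min(sqrt((ff$x_um - tt$x_um)^2 + (ff$y_um - tt$y_um)^2))
      expect_equal(got$distance_um[r], brute, tolerance = 1e-12)
    }
  }
})

test_that("distances are invariant under joint rigid transformation", {
  set.seed(67)
  tr <- make_track(x = runif(6), y = runif(6))
  fo <- data.frame(cell_id = 1L, focus_id = 1:3, x_um = runif(3),
                   y_um = runif(3))
  d0 <- nearest_focus_distances(tr, fo)$distance_um
  phi <- 0.77; tx <- 3; ty <- -1
  rot <- function(x, y) list(x = tx + cos(phi) * x - sin(phi) * y,
                             y = ty + sin(phi) * x + cos(phi) * y)
  trt <- tr; p <- rot(tr$x_um, tr$y_um); trt$x_um <- p$x; trt$y_um <- p$y
  fot <- fo; q <- rot(fo$x_um, fo$y_um); fot$x_um <- q$x; fot$y_um <- q$y
  expect_equal(nearest_focus_distances(trt, fot)$distance_um, d0,
               tolerance = 1e-12)
})

test_that("distance histograms normalize and capture anchoring contrast", {
  h1 <- distance_probability_histogram(rep(0.25, 10))
  expect_equal(sum(h1$probability), 1)
  expect_equal(h1$probability[3], 1)   # all mass in [0.2, 0.3)
  first_bins_mass <- function(preset) {
    cfg <- sim_preset(preset, seed = 68)
    cfg$n_cells <- 8L
    sim <- simulate_tracks(cfg)
    d <- quiet(nearest_focus_distances(sim$tracks, sim$foci))
    h <- distance_probability_histogram(d, bin_width = 0.1)
    sum(h$probability[h$bin_right_um <= 0.2])
  }
  expect_gt(first_bins_mass("target_plasmid"),
            first_bins_mass("nontarget_plasmid"))
})
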