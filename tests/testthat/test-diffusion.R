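test_that("displacement pooling matches hand-computed examples", {
  stat6 <- make_track(x = rep(0.3, 6), y = rep(-0.1, 6))
  expect_equal(quiet(frame_displacements(stat6)), rep(0, 10))
  walk <- make_track(x = seq(0, 0.5, by = 0.1), y = rep(0, 6))
  expect_setequal(round(quiet(frame_displacements(walk)), 10),
                  c(0.1, 0))
  expect_equal(sum(round(quiet(frame_displacements(walk)), 10) == 0.1), 5L)
  expect_error(quiet(frame_displacements(make_track(x = 1, y = 1))),
               "no adjacent-frame pairs")
  # simulated single population: sample variance = 2 D dt + 2 s_loc^2
  D <- 0.2; sl <- 0.02
  cfg <- unconfined_config(D, n_molecules = 200L, n_frames = 40L,
                           loc_noise_sigma = sl, seed = 13)
  d <- quiet(frame_displacements(simulate_tracks(cfg)$tracks))
  expect_equal(stats::var(d), 2 * D * 0.030 + 2 * sl^2, tolerance = 0.03)
})

test_that("squared displacements follow the 3-4-5 example and 4 D dt", {
  tr <- make_track(x = c(0, 0.3), y = c(0, 0.4))
  expect_equal(squared_displacements(tr), 0.25)
  expect_equal(squared_displacements(make_track(x = rep(1, 4), y = rep(1, 4))),
               rep(0, 3))
  cfg <- unconfined_config(0.15, n_molecules = 200L, n_frames = 40L, seed = 15)
  r2 <- squared_displacements(simulate_tracks(cfg)$tracks)
  expect_equal(mean(r2), 4 * 0.15 * 0.030, tolerance = 0.03)
})

test_that("sigma-to-D conversion inverts the printed diffusion rates", {
  expect_equal(sigma_to_D(0, 0.03), 0)
  expect_equal(sigma_to_D(0.037147, 0.030), 0.023, tolerance = 1e-3)
  expect_equal(sigma_to_D(0.087636, 0.030), 0.128, tolerance = 1e-3)
  expect_error(sigma_to_D(0.1, 0), "delta_t")
  expect_error(sigma_to_D(-0.1, 0.03), "sigma")
})

test_that("Gaussian mixture EM recovers two populations and handles degeneracy", {
  set.seed(16)
  x <- c(rnorm(1e4, 0, 0.02), rnorm(1e4, 0, 0.1))
  fit <- fit_gaussian_mixture(x, K = 2, delta_t = 0.030)
  expect_equal(fit$fractions, c(0.5, 0.5), tolerance = 0.05)
  expect_equal(fit$sigma, c(0.02, 0.1), tolerance = 0.05)
  expect_equal(fit$D, fit$sigma^2 / (2 * 0.030), tolerance = 1e-12)
  expect_equal(sum(fit$fractions), 1, tolerance = 1e-9)
  # degenerate sample: flagged single-component result, not a crash
  z <- fit_gaussian_mixture(rep(0, 100), K = 2, delta_t = 0.030)
  expect_equal(z$sigma, 0)
  expect_equal(z$D, 0)
  expect_match(z$warning, "degenerate")
})

test_that("EM agrees with an independent general-purpose mixture fitter", {
  suppressPackageStartupMessages(library(mclust))
  set.seed(17)
  x <- c(rnorm(8e3, 0, 0.03), rnorm(4e3, 0, 0.15))
  ours <- fit_gaussian_mixture(x, K = 2, delta_t = 0.030)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  sig_mc <- sort(sqrt(mc$parameters$variance$sigmasq))
  expect_equal(ours$sigma, sig_mc, tolerance = 0.05)
  expect_equal(sort(ours$fractions), sort(mc$parameters$pro), tolerance = 0.05)
})

test_that("fitting one population with K = 2 collapses identifiably", {
  set.seed(18)
  x <- rnorm(2e4, 0, 0.06)
  fit <- fit_gaussian_mixture(x, K = 2, delta_t = 0.030)
  collapsed <- abs(fit$sigma[2] - fit$sigma[1]) / fit$sigma[2] < 0.05 ||
    min(fit$fractions) < 0.05
  expect_true(collapsed)
})

test_that("single-population squared-displacement fit matches the closed form", {
  D <- 0.08; dt <- 0.030
  r2 <- sample_mixture_r2(2e4, 1, D, dt, seed = 19)
  fit <- fit_sqd_mixture(r2, K = 1, delta_t = dt)
  expect_equal(fit$D, D, tolerance = 0.02)
  # fitted CDF equals 1 - exp(-u / 4 D dt) at the fitted D
  u <- seq(0, stats::quantile(r2, 0.99), length.out = 50)
  a <- 4 * fit$D * dt
  emp <- stats::ecdf(r2)(u)
  expect_lt(max(abs((1 - exp(-u / a)) - emp)), 0.02)
})

test_that("three-population jump-distance fit recovers known parameters", {
  f <- c(0.34, 0.36, 0.30); D <- c(0.023, 0.128, 0.6); dt <- 0.030
  r2 <- sample_mixture_r2(3e4, f, D, dt, seed = 20)
  fit <- fit_sqd_mixture(r2, K = 3, delta_t = dt)
  expect_equal(fit$fractions, f, tolerance = 0.05)
  expect_true(all(abs(fit$D - D) / D < 0.10))
  expect_equal(sum(fit$fractions), 1, tolerance = 1e-9)
  expect_true(all(diff(fit$D) > 0))
  # localization-error correction: same mixture blurred by 20 nm noise
  sl <- 0.02
  r2n <- sample_mixture_r2(3e4, f, D, dt, seed = 20, sigma_loc = sl)
  fitn <- fit_sqd_mixture(r2n, K = 3, delta_t = dt, sigma_loc = sl)
  expect_equal(fitn$D[1], D[1], tolerance = 0.15)
})

test_that("fitted mixture CDF is monotone from 0 to 1 and label-stable", {
  r2 <- sample_mixture_r2(5e3, c(0.5, 0.5), c(0.02, 0.3), 0.030, seed = 22)
  fit <- fit_sqd_mixture(r2, K = 2, delta_t = 0.030)
  a <- 2 * fit$sigma^2
  u <- seq(0, max(r2) * 2, length.out = 200)
  cdf <- 1 - colSums(fit$fractions * exp(-outer(1 / a, u)))
  expect_true(all(diff(cdf) >= -1e-12))
  expect_equal(cdf[1], 0, tolerance = 1e-9)
  expect_gt(cdf[200], 0.99)
  # permuting the sample does not change the fit
  set.seed(23)
  fit2 <- fit_sqd_mixture(sample(r2), K = 2, delta_t = 0.030)
  expect_equal(fit2$D, fit$D, tolerance = 1e-9)
})

test_that("method-of-moments oracle agrees with the K = 1 fit", {
  r2 <- sample_mixture_r2(2e4, 1, 0.3, 0.030, seed = 24)
  fit <- fit_sqd_mixture(r2, K = 1, delta_t = 0.030)
  mom <- mean(r2) / (4 * 0.030)
  expect_equal(fit$D, mom, tolerance = 0.02)
})

test_that("global fit shares D across conditions and recovers fractions", {
  dt <- 0.030; D <- c(0.02, 0.12, 0.6)
  fA <- c(0.5, 0.3, 0.2); fB <- c(0.2, 0.3, 0.5)
  r2 <- list(A = sample_mixture_r2(1e4, fA, D, dt, seed = 25),
             B = sample_mixture_r2(1e4, fB, D, dt, seed = 26))
  fits <- fit_sqd_global(r2, K = 3, delta_t = dt)
  expect_identical(fits$A$D, fits$B$D)
  expect_equal(fits$A$fractions, fA, tolerance = 0.05)
  expect_equal(fits$B$fractions, fB, tolerance = 0.05)
  expect_true(all(abs(fits$A$D - D) / D < 0.15))
  # identical mixtures: shared fit close to individual fits
  r2id <- list(A = sample_mixture_r2(1e4, fA, D, dt, seed = 27),
               B = sample_mixture_r2(1e4, fA, D, dt, seed = 28))
  g <- fit_sqd_global(r2id, K = 3, delta_t = dt)
  ind <- fit_sqd_mixture(r2id$A, K = 3, delta_t = dt)
  expect_equal(g$A$D, ind$D, tolerance = 0.25)
  expect_error(fit_sqd_global(list(A = r2$A), K = 3, delta_t = dt),
               "at least 2 conditions")
})

test_that("MSD obeys stationary, ballistic and Brownian closed forms", {
  stat <- make_track(x = rep(0.5, 10), y = rep(0.5, 10))
  m0 <- msd(stat, 5, 0.030)
  expect_true(all(m0$msd_um2 == 0))
  expect_true(all(diff(m0$n_pairs) <= 0))
  d <- 0.05
  ball <- make_track(x = seq(0, by = d, length.out = 20), y = rep(0, 20))
  mb <- msd(ball, 8, 0.030)
  expect_equal(mb$msd_um2, (seq_len(8) * d)^2, tolerance = 1e-12)
  cfg <- unconfined_config(0.1, n_molecules = 1200L, n_frames = 25L,
                           seed = 29, n_cells = 1L)
  sim <- simulate_tracks(cfg)
  mc <- msd(sim$tracks, 6, 0.030)
  est <- d_from_msd(mc, n_fit_points = 4)
  expect_equal(est$D, 0.1, tolerance = 0.05)
  expect_equal(est$offset, 0, tolerance = 0.003)
})

test_that("D-from-MSD flags ballistic curves and clips negative slopes", {
  exact <- data.frame(lag_frames = 1:6, lag_s = (1:6) * 0.030,
                      msd_um2 = 4 * 0.1 * (1:6) * 0.030, n_pairs = 100L,
                      sem_um2 = 0)
  class(exact) <- c("msd_curve", "data.frame")
  est <- d_from_msd(exact, 4)
  expect_equal(est$D, 0.1, tolerance = 1e-9)
  expect_equal(est$offset, 0, tolerance = 1e-9)
  ball <- make_track(x = seq(0, by = 0.05, length.out = 30), y = rep(0, 30))
  eb <- d_from_msd(msd(ball, 10, 0.030), 10)
  expect_lt(eb$r_squared, 0.96)   # linear fit to a quadratic curve
  neg <- exact
  neg$msd_um2 <- rev(neg$msd_um2)
  en <- d_from_msd(neg, 4)
  expect_equal(en$D, 0)
  expect_true(en$clipped)
  expect_error(d_from_msd(exact, 10), "fewer lags")
})
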