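# End-to-end workflow: simulate -> analyze -> report, each step driven by a
# plain-text config and writing machine-readable tables plus a provenance
# record. These functions back the command-line script in inst/cli/.

#' Read / write a simulation config as YAML
#'
#' The YAML file mirrors the `sim_config` fields; `mixture` is given as
#' `fractions` and `D` lists plus the shared `delta_t`, `geometry` as
#' `length`, `radius`.
#'
#' @param path YAML file path.
#' @return `read_sim_config` returns a `sim_config`; `write_sim_config`
#'   returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  dt <- if (!is.null(y$delta_t)) y$delta_t else 0.030
  mix <- if (!is.null(y$mixture))
    population_mixture(unlist(y$mixture$fractions), unlist(y$mixture$D), dt)
  else population_mixture(c(0.34, 0.36, 0.30), c(0.023, 0.128, 0.6), dt)
  geom <- if (!is.null(y$geometry))
    cell_geometry(y$geometry$length, y$geometry$radius)
  else cell_geometry(2.5, 0.5)
  args <- y[setdiff(names(y), c("mixture", "geometry"))]
  do.call(sim_config, c(list(mixture = mix, geometry = geom), args))
}

#' @rdname read_sim_config
#' @param config A `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  y <- list(delta_t = config$delta_t, n_frames = config$n_frames,
            n_cells = config$n_cells, n_molecules = config$n_molecules,
            loc_noise_sigma = config$loc_noise_sigma,
            survival_prob = config$survival_prob,
            bleach_phase_frames = config$bleach_phase_frames,
            n_foci = config$n_foci, anchor_fraction = config$anchor_fraction,
            anchor_radius = config$anchor_radius,
            polar_bias = config$polar_bias, cell_jitter = config$cell_jitter,
            min_steps = config$min_steps, channel = config$channel,
            condition = config$condition, seed = config$seed,
            mixture = list(fractions = as.numeric(config$mixture$fractions),
                           D = as.numeric(config$mixture$D)),
            geometry = list(length = config$geometry$length,
                            radius = config$geometry$radius))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Simulate a dataset and write all interface files
#'
#' Runs [simulate_tracks()] and writes `tracks.tsv`, `foci.tsv`,
#' `geometry.tsv`, `truth.tsv`, the config as `config.yaml` and a
#' `provenance.json` record (config, seed, package version, timestamp).
#'
#' @param config A `sim_config`, a preset name, or a path to a YAML config.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional override of the config's seed.
#' @return The simulation list from [simulate_tracks()], invisibly.
#' @export
run_simulate <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) {
    config <- if (file.exists(config)) read_sim_config(config)
              else sim_preset(config)
  }
  if (!is.null(seed)) config$seed <- as.integer(seed)
  validate_sim_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_tracks(config)
  write_tracks(sim$tracks, file.path(out_dir, "tracks.tsv"))
  write_foci(sim$foci, file.path(out_dir, "foci.tsv"))
  write_geometries(sim$geometries, file.path(out_dir, "geometry.tsv"))
  write_results(sim$truth, file.path(out_dir, "truth.tsv"))
  write_sim_config(config, file.path(out_dir, "config.yaml"))
  prov <- list(tool = "trackmix",
               version = as.character(utils::packageVersion("trackmix")),
               seed = config$seed, condition = config$condition,
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(sim)
}

#' Analyze a track dataset end to end
#'
#' Pipeline: minimum-step filter -> pooled displacements -> K-component
#' jump-distance mixture fit (or a global fit with shared D when several
#' datasets are given) -> two-population Gaussian mixture -> MSD ->
#' standardized-cell density map -> dwelling classification (and foci from
#' dwelling tracks if no focus table is given) -> nearest-focus distance
#' histogram. Every numeric result is written as a delimited table.
#'
#' @param tracks A track table, a path to one, or a named list of either
#'   (multiple conditions; triggers the global fit when `global = TRUE`).
#' @param geometries Geometry table or path (required for density maps).
#' @param foci Optional focus table or path; if absent, foci are derived
#'   from dwelling tracks.
#' @param out_dir Output directory for result tables.
#' @param delta_t Frame interval in seconds.
#' @param k Number of diffusive populations for the jump-distance fit.
#' @param global Share D across conditions when several are given.
#' @param min_steps Minimum steps per track.
#' @param points_per_track Points per track entering the distance analysis.
#' @param sigma_loc Localization error passed to the mixture fit (0 = no
#'   correction).
#' @return A list of results (fits, msd, density map, distances), invisibly.
#' @export
run_analyze <- function(tracks, geometries = NULL, foci = NULL,
                        out_dir = NULL, delta_t = 0.030, k = 3L,
                        global = FALSE, min_steps = 5L,
                        points_per_track = 5L, sigma_loc = 0) {
  load_tr <- function(x) if (is.character(x)) read_tracks(x, delta_t) else x
  multi <- is.list(tracks) && !is.data.frame(tracks)
  tr_list <- if (multi) lapply(tracks, load_tr) else list(data = load_tr(tracks))
  tr_list <- lapply(tr_list, filter_min_steps, min_steps = min_steps)
  if (is.character(geometries)) geometries <- read_geometries(geometries)
  if (is.character(foci)) foci <- read_foci(foci)

  r2 <- lapply(tr_list, squared_displacements)
  fits <- if (multi && global && length(tr_list) >= 2L) {
    fit_sqd_global(r2, K = k, delta_t = delta_t, sigma_loc = sigma_loc)
  } else {
    lapply(r2, fit_sqd_mixture, K = k, delta_t = delta_t,
           sigma_loc = sigma_loc)
  }
  gmm <- lapply(tr_list, function(tt)
    fit_gaussian_mixture(frame_displacements(tt), K = 2L, delta_t = delta_t))
  msds <- lapply(tr_list, msd, max_lag_frames = 10L, delta_t = delta_t)
  dmaps <- if (!is.null(geometries))
    lapply(tr_list, function(tt) density_map(tt, geometries)) else NULL
  dwell <- lapply(tr_list, classify_dwelling)
  dist_hists <- NULL
  distances <- NULL
  if (is.null(foci)) {
    # derive reference foci from dwelling tracks of the first condition
    foci_est <- foci_from_dwelling(tr_list[[1]], dwell[[1]])
  } else foci_est <- foci
  if (!is.null(foci_est) && nrow(foci_est) > 0) {
    distances <- lapply(names(tr_list), function(nm) {
      d <- try(suppressMessages(
        nearest_focus_distances(tr_list[[nm]], foci_est,
                                points_per_track = points_per_track)),
        silent = TRUE)
      if (inherits(d, "try-error")) NULL else d
    })
    names(distances) <- names(tr_list)
    ok <- !vapply(distances, is.null, logical(1))
    if (any(ok))
      dist_hists <- do.call(rbind, lapply(names(tr_list)[ok], function(nm)
        distance_probability_histogram(distances[[nm]], condition = nm)))
  }
  results <- list(fits = fits, gmm = gmm, msd = msds, density = dmaps,
                  dwelling = dwell, foci = foci_est,
                  distances = distances, distance_histograms = dist_hists)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    ft <- do.call(rbind, lapply(names(fits), function(nm)
      fit_table(fits[[nm]], condition = nm)))
    write_results(ft, file.path(out_dir, "mixture_fits.tsv"))
    gt <- do.call(rbind, lapply(names(gmm), function(nm)
      fit_table(gmm[[nm]], condition = nm)))
    write_results(gt, file.path(out_dir, "gaussian_fits.tsv"))
    mt <- do.call(rbind, lapply(names(msds), function(nm)
      cbind(as.data.frame(msds[[nm]]), condition = nm)))
    write_results(mt, file.path(out_dir, "msd.tsv"))
    rt <- do.call(rbind, lapply(names(fits), function(nm)
      cbind(fits[[nm]]$residuals, condition = nm)))
    write_results(rt, file.path(out_dir, "jump_histograms.tsv"))
    dw <- do.call(rbind, lapply(names(dwell), function(nm)
      cbind(dwell[[nm]], condition = nm)))
    write_results(dw, file.path(out_dir, "dwelling.tsv"))
    if (!is.null(foci_est) && nrow(foci_est) > 0)
      write_foci(foci_est, file.path(out_dir, "foci_used.tsv"))
    if (!is.null(dist_hists))
      write_results(dist_hists, file.path(out_dir, "distance_histograms.tsv"))
    if (!is.null(dmaps)) {
      dm <- do.call(rbind, lapply(names(dmaps), function(nm) {
        m <- dmaps[[nm]]
        uc <- (m$u_edges[-1] + m$u_edges[-length(m$u_edges)]) / 2
        vc <- (m$v_edges[-1] + m$v_edges[-length(m$v_edges)]) / 2
        d <- expand.grid(u = uc, v = vc)
        d$density <- as.vector(m$density)
        d$condition <- nm
        d
      }))
      write_results(dm, file.path(out_dir, "density_maps.tsv"))
    }
  }
  invisible(results)
}

#' Render result figures from an analysis directory
#'
#' Reads the tables written by [run_analyze()] and produces the figure set:
#' jump-distance histograms with fitted curves and residual panels, a
#' fraction-versus-D bubble plot, MSD curves with SEM bars,
#' standardized-cell heat maps, and nearest-focus distance histograms.
#' Missing tables are reported by name.
#'
#' @param results_dir Directory containing the analysis tables.
#' @param out_dir Output directory for PDF figures (default: `results_dir`).
#' @return Character vector of written figure paths, invisibly.
#' @export
run_report <- function(results_dir, out_dir = results_dir) {
  need <- c("mixture_fits.tsv", "jump_histograms.tsv", "msd.tsv")
  missing <- need[!file.exists(file.path(results_dir, need))]
  if (length(missing))
    stop("missing result tables in ", results_dir, ": ",
         paste(missing, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  save_fig <- function(p, name, w = 6, h = 4) {
    path <- file.path(out_dir, name)
    grDevices::pdf(path, width = w, height = h)
    print(p)
    grDevices::dev.off()
    written <<- c(written, path)
  }
  ft <- read_results(file.path(results_dir, "mixture_fits.tsv"))
  jh <- read_results(file.path(results_dir, "jump_histograms.tsv"))
  fits <- lapply(split(ft, ft$condition), function(d) {
    d <- d[order(d$component), ]
    res <- jh[jh$condition == d$condition[1],
              c("bin_left_um", "bin_right_um", "observed", "fitted", "residual")]
    .mixture_fit(nrow(d), d$fraction, d$sigma_um, 0.030, d$method[1],
                 residuals = res, D = d$D_um2_s)
  })
  for (nm in names(fits)) {
    p <- plot_jump_histogram(fits[[nm]], title = paste("Jump distances:", nm))
    save_fig(p$histogram, paste0("jump_histogram_", nm, ".pdf"))
    save_fig(p$residuals, paste0("jump_residuals_", nm, ".pdf"), h = 2.2)
  }
  save_fig(plot_bubble(fits), "bubble.pdf")
  mt <- read_results(file.path(results_dir, "msd.tsv"))
  curves <- lapply(split(mt, mt$condition), function(d) {
    d <- d[setdiff(names(d), "condition")]
    class(d) <- c("msd_curve", "data.frame"); d
  })
  save_fig(plot_msd(curves), "msd.pdf")
  dm_path <- file.path(results_dir, "density_maps.tsv")
  if (file.exists(dm_path)) {
    dm <- read_results(dm_path)
    for (nm in unique(dm$condition)) {
      d <- dm[dm$condition == nm, ]
      nu <- length(unique(d$u)); nv <- length(unique(d$v))
      m <- structure(list(density = matrix(d$density, nu, nv),
                          u_edges = seq(-0.5, 0.5, length.out = nu + 1),
                          v_edges = seq(-0.5, 0.5, length.out = nv + 1),
                          n_cells = NA_integer_), class = "cell_map")
      m$n_cells <- 0L
      save_fig(plot_density_map(m), paste0("density_map_", nm, ".pdf"))
    }
  }
  dh_path <- file.path(results_dir, "distance_histograms.tsv")
  if (file.exists(dh_path))
    save_fig(plot_distance_histogram(read_results(dh_path)),
             "distance_histogram.pdf")
  invisible(written)
}
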