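# trackmix

Simulation and mixture-based diffusion analysis of single-molecule tracks
in rod-shaped bacteria.

Single-molecule microscopy (slimfield SMM) follows individual fluorescent
proteins — e.g. CRISPR effector complexes (crRNPs) or the replisome
clamp-loader subunit DnaX — at ~30 ms frame intervals inside cells of about
1 × 2.5 µm. The scientific readout is population structure: what fraction of
molecules is bound (slow), scanning DNA (intermediate), or freely diffusing
(mobile), and how those fractions shift between experimental conditions.
`trackmix` is for microscopists and quantitative biologists who want a
tested, fully reproducible version of that analysis plus a ground-truth
simulator to validate it.

## The model

Molecules belong to one of *K* Brownian populations with fractions *f_i*
and diffusion coefficients *D_i*. Per-coordinate frame-to-frame steps are
N(0, σ_i²) with σ_i² = 2 D_i Δt (equivalently D_i = σ_i²/2Δt), and the
squared 2D jump r² is exponential per population, giving the mixture CDF

    P(r² ≤ u) = 1 − Σ_i f_i · exp(−u / (4 D_i Δt + 4 σ_loc²))

which `fit_sqd_mixture()` fits by variance-weighted least squares on the
empirical CDF (localization-error term σ_loc optional). Companion
estimators: a zero-mean Gaussian mixture EM on pooled 1D displacements
(`fit_gaussian_mixture()`, the classical static/mobile split), global fits
sharing D_i across conditions (`fit_sqd_global()`), and MSD-versus-lag
analysis (`msd()`, `d_from_msd()`). Spatial statistics cover
standardized-cell track-density maps, dwelling classification, focus
detection from dwelling tracks, and nearest-focus distance histograms
(D = √((x_focus − x_i)² + (y_focus − y_i)²), minimum over foci of the same
cell). The simulator generates reflected Brownian motion in spherocylinders
with photobleaching, localization noise, focus-anchored molecules and
per-condition presets, all with complete ground truth.

## Worked example

```r
library(trackmix)

cfg <- sim_preset("wildtype", seed = 1)   # 3 populations, 30 ms frames
cfg$loc_noise_sigma <- 0                  # benchmark: no localization noise
cfg$n_cells <- 40L
sim    <- simulate_tracks(cfg)
tracks <- filter_min_steps(sim$tracks, 5)
fit    <- fit_sqd_mixture(squared_displacements(tracks), K = 3,
                          delta_t = 0.030)
print(fit)
```

```
mixture_fit (sqd_cdf_ls), K = 3, delta_t = 0.03 s
  component 1: f = 0.349, D = 0.02181 um^2/s, sigma = 0.03618 um
  component 2: f = 0.401, D = 0.1255 um^2/s, sigma = 0.08677 um
  component 3: f = 0.250, D = 0.5219 um^2/s, sigma = 0.177 um
  max |histogram residual| = 0.0019
```

The generative truth here is f = (0.34, 0.36, 0.30) with
D = (0.023, 0.128, 0.6) µm²/s: the slow and intermediate coefficients and
all three fractions are recovered closely; the mobile coefficient reads low
because a molecule at 0.6 µm²/s is strongly confined by a 1 µm-wide cell
(its lag-1 MSD genuinely falls below 4DΔt). The residual line says the
50-bin jump-distance histogram deviates from the fitted mixture by at most
0.0019 — far inside the ±0.02 band conventionally taken as an adequate fit.

MSD analysis of the same tracks:

```r
est <- d_from_msd(msd(tracks, max_lag_frames = 6, delta_t = 0.030))
#> MSD slope D = 0.1581 um^2/s, offset = 0.00390 um^2
```

a single effective coefficient near the fraction-weighted mixture average,
illustrating why the mixture fit, not the ensemble MSD, is the right tool
for population structure.

A command-line wrapper covers the full workflow:

```sh
Rscript inst/cli/trackmix.R simulate --preset target_plasmid --seed 1 --out sim/
Rscript inst/cli/trackmix.R analyze  --tracks sim/tracks.tsv \
        --geometry sim/geometry.tsv --foci sim/foci.tsv --out results/
Rscript inst/cli/trackmix.R report   --results results/
```

`report` renders jump-distance histograms with fitted curves and residual
panels, fraction-versus-D bubble plots, MSD curves with SEM bars,
standardized-cell heat maps, and nearest-focus distance histograms.

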