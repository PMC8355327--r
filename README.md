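# ertrack

Quantification of endoplasmic reticulum (ER) tubule networks and their
dynamics from fluorescence microscopy data.

ER tubules are ~100 nm membrane cylinders that meet at junctions and
fluctuate continuously in live cells.  On the single-tubule scale they
behave as semiflexible polymers: an established tubule (connected to the
network at both ends) oscillates transversely about a mean contour, partly
thermally and partly driven by motors and organelle contact sites.
`ertrack` provides the full measurement chain for this system:

* **Network morphometrics** from traced still images (SOAX snake output):
  tubule contour lengths `L` and end-to-end distances `R`, junction
  coordination numbers and angles, and the population persistence length
  `Lp` from the worm-like chain relation
  `⟨R²⟩ = 2·Lp·(L − Lp·(1 − exp(−L/Lp)))`.
* **Sub-pixel point tracking** of a tubule position along a user-drawn
  line: bicubic profile extraction, kriging upsampling to 100 values, an
  SNR gate calibrated on simulated profiles, and a robust
  (Cauchy-weighted) Gaussian-with-offset fit.
* **MSD analysis**: time-averaged `⟨Δr²(τ)⟩`, weighted log–log power-law
  fits of the anomalous exponent `α` (α≈1 Brownian; 3/4 thermal
  untensioned filament; 1/2 tension-dominated), and lognormal population
  summaries.
* **Contour tracking** with an open active contour, backbone statistics,
  and a bias-corrected skewness test (`|z| > 3.29`) that flags
  activity-driven transverse fluctuations, plus the line density of
  skewed points.
* **Fourier cosine-mode decomposition** of the tangent angle
  (`a_n = √(2/L) Σ θ_k Δs_k cos(nπs_k/L)`) and a sustained-curvature
  classification (`|⟨a_n⟩| − 1.5·σ > 0` for any mode n ≥ 1).
* **Association-rule mining** over binary tubule properties (sustained
  curvature, peripheral position, MSD exponent ≥ 0.4, significant
  skewness) with support/confidence/lift.
* A **filament simulator** (overdamped semiflexible bead chain with
  tension, thermal noise, and bursty active kicks) and a **video
  renderer** (Gaussian PSF line source + noise) providing ground truth
  for every stage.

## Worked example

Recover a known persistence length from simulated worm-like chains, and a
diffusive exponent from a simulated Brownian point:

```r
library(ertrack)

ens <- wlc_ensemble(Lp = 5, Ls = seq(0.5, 4, by = 0.5), n_rep = 1250,
                    n_points = 40, seed = 1)
fit_persistence_length(ens)
#> Worm-like chain persistence length fit (10000 tubules)
#>   Lp = 5.154 +/- 0.045 um

track <- simulate_brownian_track(D = 0.01, dt = 0.03, n_frames = 1000,
                                 seed = 1)
fit_msd_exponent(compute_msd(track))
#> MSD power law: alpha = 0.9809 +/- 0.0019 (5 lags, tau in [0.03, 0.15] s)
```

`Lp` lands within ~3% of the generating 5 µm, and the Brownian control
fits α ≈ 1 as diffusion requires (a single 1000-frame track carries an
irreducible exponent scatter of about ±0.03).

Tracking a rendered video end to end:

```r
cfg <- filament_sim_config(n_beads = 40, L = 39, Lp = 5, tension = 90,
                           kT = 6, dt = 0.001, substeps = 100,
                           n_frames = 25, burn_in = 60, ends = "pinned",
                           seed = 8)
truth <- simulate_filament_dynamics(cfg)
# place the filament inside a 56 x 64 px frame and render it
placed <- contour_series(lapply(truth$contours, function(ct)
  filament_contour(cbind(ct$points[, 1] + 12, ct$points[, 2] + 28))),
  times = truth$times)
vid <- render_video(placed, render_config(image_size = c(56, 64),
                                          peak = 200, gaussian_sd = 1))
series <- track_contour_video(vid$video, rbind(c(12, 28), c(51, 28)),
                              pixel_size = 1)
modes <- decompose_series(series)
sustained_curvature(modes)$sustained           # needs >= 20 frames
```

A thin command-line wrapper with subcommands (`network`, `track-point`,
`msd`, `track-contour`, `modes`, `mine`, `simulate`, `render`,
`calibrate-snr`) lives at `inst/cli/ertrack`; every run writes a JSON
manifest with inputs, parameters and the seed.

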