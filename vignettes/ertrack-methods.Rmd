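---
title: "Quantifying ER tubule networks and dynamics with ertrack"
author: "ertrack maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ER tubule networks and dynamics with ertrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ertrack)
```

# Scope and model

The endoplasmic reticulum (ER) of animal cells is a network of membrane
tubules (roughly 100 nm in diameter) meeting at junctions.  On the scale of
single tubules the network behaves like a collection of semiflexible
polymers: an *established* tubule — one connected to the network at both
ends throughout an observation — fluctuates transversely about a mean
contour, driven partly by thermal agitation of the cytoplasm and partly by
active machinery (motor proteins, contact sites with other organelles).
`ertrack` implements a complete measurement chain for this system:

1. **Network morphometrics** from traced still images: tubule contour
   lengths `L`, end-to-end distances `R`, junction coordination numbers and
   inter-tubule angles, and the population persistence length.
2. **Point tracking**: sub-pixel localisation of one tubule position along a
   user-drawn line, frame by frame.
3. **MSD analysis**: time-averaged mean squared displacement and the
   anomalous exponent `alpha`.
4. **Contour tracking**: whole-tubule open-active-contour tracking,
   backbone statistics, and a skewness test that flags activity-driven
   (asymmetric) fluctuations.
5. **Fourier mode decomposition** of the tangent angle and a
   sustained-curvature classification.
6. **Itemset mining** of binary per-tubule property profiles.
7. A **simulator and renderer** that generate ground-truth filament data
   and microscopy-like videos, used to validate and calibrate every stage.

Coordinates are pixels with the origin at the centre of the top-left pixel,
x along columns, y along rows; physical lengths enter only through the
pixel size (micrometres per pixel; 0.104 is typical of the videos this
workflow targets).

# Persistence length

For a worm-like chain with persistence length $L_p$ the mean square
end-to-end distance at contour length $L$ is

$$\langle R^2 \rangle = 2 L_p \left( L - L_p (1 - e^{-L/L_p}) \right),$$

which interpolates between the rigid-rod limit $L^2$ ($L \ll L_p$) and the
ideal-chain limit $2 L_p L$ ($L \gg L_p$).  `fit_persistence_length()` fits
this relation to per-tubule $(L, R^2)$ pairs by Levenberg–Marquardt
nonlinear least squares, starting from $L_p = \mathrm{median}(L)$ with box
bounds $(10^{-3}, 10^4)$ µm.  Fits that hit the upper bound are flagged
near-rigid rather than reported as estimates.  Both unbinned fitting (the
default) and equal-count binning of $L$ with bin-mean $R^2$ are supported;
on exact model data they agree, and on sampled worm-like chains the
unbinned fit recovers the generating $L_p$ within a few percent with
$10^4$ chains.  Whether the relation above (derived in 3D) is strictly
appropriate for contours projected into the image plane is a modelling
choice; the package applies it as stated, and the chain sampler offers an
`eq1` convention (tangent correlation $e^{-s/L_p}$) for which the relation
is exact in 2D, alongside the standard planar convention
($e^{-s/2L_p}$).

```{r lp-example}
ens <- wlc_ensemble(5, Ls = seq(0.5, 4, by = 0.5), n_rep = 250,
                    seed = 42)
fit_persistence_length(ens)
```

# Junction geometry

Junction membership uses a 2-pixel search radius (configurable): a tubule
end belongs to a junction if it lies within the radius.  Each member
contributes a direction from an orthogonal least-squares line through its
5 contour points nearest the junction (all points when the tubule is
shorter), oriented away from the junction; orthogonal regression avoids
the degeneracy of `y ~ x` fits for near-vertical tubules.  Two-way
junctions report the single angle between the two rays in (0°, 180°];
higher-order junctions report adjacent angles between azimuthally ordered
rays.  Angles are invariant under rigid motions of the network to
numerical precision.

# Sub-pixel point tracking

Each frame is band-pass filtered (Gaussian frequency-domain filter,
default pass band between 1 and 10 pixels) and background-subtracted
(grayscale opening with a disc, default radius 50 px) before profile
extraction.  The intensity along the user's line is sampled by Catmull–Rom
bicubic interpolation, then upsampled to 100 values by ordinary kriging
with a Gaussian covariance (range twice the mean sample spacing, zero
nugget) and a linear drift term, so the interpolant passes through the raw
samples and reproduces linear ramps exactly; if the kriging system's
condition number exceeds $10^{10}$ a cubic-spline fallback is used and
tagged.  A signal-to-noise gate

$$\mathrm{SNR} = \frac{\max(\text{smoothed profile}) -
\mathrm{median}(\text{profile})}{1.4826 \cdot
\mathrm{MAD}(\text{profile} - \text{smoothed profile})}$$

rejects frames too noisy to fit; the smoothing window defaults to one
tenth of the profile length so that interpolation-scale wiggles count as
noise.  The threshold is not hard-coded: `calibrate_snr_threshold()` sweeps
noise levels on rendered tubule cross-sections and returns the smallest
SNR at which the median absolute centre error is at most 1% of the tubule
width.  Gated profiles are fitted with a Gaussian plus offset by
iteratively reweighted least squares with Cauchy weights (tuning constant
2.385), making the centre robust to single outlying samples; fits whose
width collapses below 0.5 px or exceeds the profile span are flagged
invalid.  Invalid frames carry no position and are excluded from the MSD
pairwise — interpolating them would bias short lags.

# MSD and the anomalous exponent

The two-dimensional time-averaged MSD uses all valid ordered frame pairs
per lag; lags with fewer than 3 pairs are dropped.  The exponent is the
slope of a weighted linear regression of $\log \mathrm{MSD}$ on
$\log \tau$ with pair-count weights.  The default fit window covers the
first five lag points (capped at one quarter of the track duration).
This choice is deliberate: long-lag values of a single-trajectory
time-averaged MSD are few-sample and strongly correlated, so the sampling
variance of the fitted exponent *grows monotonically* with the upper
cutoff — on simulated 1000-frame Brownian controls the exponent's standard
deviation is about 0.03 for the default window, 0.04 when the window
extends to the 10th lag, and 0.14 when it extends to a quarter of the
duration.  Even at the default, a single 1000-frame trajectory carries an
irreducible exponent scatter of ~0.03; population statements should pool
tracks.  When localization noise is appreciable the MSD has a floor of
$4\sigma_{loc}^2$ that biases short lags downward; in that case supply a
window starting where the MSD clears the floor.  For filament-regime
analyses the physically motivated window of `intermediate_lag_window()`
applies instead (below).  Population summaries fit a lognormal to the
exponents by maximum likelihood on the samples (bin-free and
reproducible; a histogram least-squares option exists for comparison),
report the distribution mean with a delta-method standard error, and
classify exponents as sub-diffusive ($\alpha < 1$), super-diffusive
($1 < \alpha < 2$), with an additional strongly sub-diffusive cut at
$\alpha < 0.4$ ($\alpha \ge 0.4$ counts as thermalised-or-active in the
property matrix).

# Contour tracking

`evolve_open_contour()` is a discrete open snake: internal energy with a
first-difference (stretching) and second-difference (bending) penalty, an
external force equal to the gradient of the Gaussian-smoothed image
normalised to unit maximum magnitude, and a semi-implicit update with
fixed-step arclength bookkeeping.  Two details matter for open filaments:

* **Endpoints** are excluded from the implicit internal step — otherwise
  the elastic term steadily contracts the snake along the ridge — and move
  under the external force plus an outward tangential *stretching* force
  proportional to the local normalised intensity.  Ends therefore extend
  along a bright ridge and come to rest at its tip, where the inward
  intensity-gradient pull balances the stretch.
* **Resampling** to the fixed arclength step happens only when the point
  spacing has drifted beyond ±50%: resampling a polyline by linear
  interpolation cuts corners, and doing it every iteration erodes genuine
  curvature.

Video tracking initialises each frame from the previous frame's converged
contour (the user supplies endpoints for frame 1 only).  A length-jump
guard (default 20% frame-to-frame change) re-evolves suspicious frames
with four-fold internal weights and, if the jump persists, keeps the
previous contour and flags the frame, suppressing spurious length changes
from tracking errors.

Backbone statistics resample all frames to a common number of points,
establish correspondence by fractional arclength, compute the per-point
mean contour (the backbone), and rotate all frames rigidly so the backbone
endpoints lie on the x-axis; transverse displacement is then the
y-deviation from the backbone.  Per point the package reports the
population variance and the bias-corrected skewness

$$s = \frac{\sqrt{n(n-1)}}{n-2}\,\frac{m_3}{m_2^{3/2}}$$

with z-score $s/\sigma_s$ against the standard error of skewness.  The
standard (Cramér) form
$\sigma_s = \sqrt{6n(n-1)/((n-2)(n+1)(n+3))}$ is the default; an
alternative "as-printed" form with the radical over the numerator only is
available for comparison but is orders of magnitude smaller (0.020 vs
0.687 at $n = 10$) and would declare almost everything significant.  A
point is significantly skewed when $|z| > 3.29$, a deliberately strict
critical value: for large $n$ the SES becomes tiny and the conventional
1.96 would reject the symmetric null for trivial asymmetries.  Thermal
(symmetric) fluctuations leave skewness at noise level; sustained
one-sided forcing shifts part of the displacement distribution to one
side and is detected.  The skewness z-test assumes approximately
independent samples: frames should be spaced by at least a few relaxation
times of the slowest tubule mode, otherwise the effective sample size is
smaller than $n$ and the false-positive rate rises.  The line density of
skewed points is the count of significant points divided by the backbone
length in micrometres.

# Fourier modes and sustained curvature

Tangent angles $\theta_k$ (two-argument arctangent, unwrapped — the
single-argument form is ambiguous for steep segments), segment lengths
$\Delta s_k$ and arclength midpoints $s_k$ define the cosine-mode
amplitudes

$$a_n = \sqrt{2/L} \sum_k \theta_k\, \Delta s_k \cos(n\pi s_k/L).$$

Cosine modes suit filaments whose ends are free to move with the network.
The mode count obeys two sampling caps: $n \le L/\max_k \Delta s_k$ (two
segments per wavelength; the largest segment is the conservative choice
for non-uniform sampling) and $n \le N - 2$ for $N$ segments; ten modes
are used when both allow it.  Reconstruction is
$\theta(s) = \sqrt{2/L}\,(a_0/2 + \sum_{n\ge1} a_n \cos(n\pi s/L))$: the
zeroth mode (mean orientation) enters with the standard cosine-series
factor 1/2, which makes decompose-then-reconstruct a projection — applying
it twice equals applying it once, and truncation only removes tangent
energy.  A mode shows *sustained curvature* when
$|\langle a_n \rangle| - 1.5\,\sigma_{a_n} > 0$; mode 0 is excluded (any
straight but tilted tubule has $a_0 \ne 0$), and the tubule is flagged
when any mode $n \ge 1$ qualifies.  Under a Gaussian amplitude
distribution the 1.5-standard-deviation rule corresponds to the amplitude
falling on one side of zero in roughly 93% of frames (one-sided normal
tail); because empirical amplitude distributions are heavier-tailed the
observed one-sided fraction at the detection boundary is nearer 87%, so
the per-mode report includes the empirical one-sided fraction alongside
the flag.

# Peripheral classification and rule mining

With nucleus and cell-edge boundary polygons, each backbone point gets a
normalised depth $d = d_{nuc}/(d_{nuc} + d_{edge})$ (0 on the nuclear
envelope, 1 on the cell edge); a tubule is peripheral when its mean depth
is at least 0.9 — the outermost 10% of the nucleus-to-edge distance.  Mean
aggregation is the documented default; a max-depth option exists because
"resides in the outermost band" could also be read as deepest-point
membership.

The property matrix has one row per tubule and 8 binary columns — presence
and absence of sustained curvature, MSD exponent ≥ 0.4, peripheral
position, and significant skewness, in the fixed order of
`property_columns()`.  Rule mining enumerates all itemsets exhaustively
(at most $2^8 - 1$), keeps those with support ≥ 0.1, evaluates every
antecedent/consequent bipartition, and keeps rules with confidence ≥ 0.9;
lift is support(A∪B)/(support(A)·support(B)).  The low support floor lets
rules involving rare properties surface; the high confidence floor keeps
only near-implications.  Itemsets containing both the presence and the
absence of one property have support 0 by construction and are skipped as
an optimisation.  The implementation is checked against an independent
brute-force enumerator on random structurally valid matrices; raising
either threshold never adds a rule.

# The simulator

The simulator integrates the *transverse* dynamics of a semiflexible
filament in the weakly-bending representation: beads at fixed axial
positions with overdamped Langevin dynamics in y,

$$\gamma_b\, \mathrm{d}y = (F_{bend} + F_{tens} + F_{act})\,\mathrm{d}t +
\sqrt{2 k_B T \gamma_b\, \mathrm{d}t}\;\eta,$$

with the bending force from the discrete squared-curvature energy
(rigidity $\kappa = L_p k_B T$), the tension force from the discrete
stretching energy, free or pinned ends, and reduced units (bead spacing,
thermal energy, and drag per unit length all 1 unless configured).  This
linear dynamics possesses exactly the two scaling regimes of interest —
midpoint transverse MSD $\propto \tau^{3/4}$ for bending-dominated and
$\propto \tau^{1/2}$ for tension-dominated filaments at lags between the
shortest and longest relaxation times — and has an exact mode-by-mode
Ornstein–Uhlenbeck solution against which the integrator was verified.
Longitudinal bead motion is neglected; this is the standard approximation
for small transverse fluctuations and means the simulator does not emulate
sliding or extension events.  An explicit-Euler stability bound
($\mathrm{d}t\,\lambda_{max}/\gamma_b < 2$) is checked up front, and a
runtime guard aborts if any deterministic bead displacement exceeds the
bead spacing.  Runs are bit-reproducible given the configuration (the
seed is part of it); `burn_in` frames can be discarded so recording starts
from an equilibrated state.

**Active forcing** is an on/off telegraph process at chosen beads:
exponential dwell times (`tau_on`, `tau_off`) and a constant one-sided
amplitude while on.  A Gaussian (e.g. Ornstein–Uhlenbeck) force on a
linear chain would yield Gaussian — hence unskewed — displacements no
matter its correlation time; bursty one-sided forcing is the minimal
model that produces the skewed transverse displacements the skewness test
is designed to detect.

Reference conditions are frozen as constructors:

* `thermal_filament_config()` — 64 beads, untensioned, $L_p/L \approx
  0.16$, free ends, 30 000 frames at 0.05 time units.  The fitted window
  of `intermediate_lag_window()` spans 10 frame intervals to 1% of the
  track duration (the slowest bending mode relaxes far beyond the run, so
  the duration cap binds): the lower edge clears the fastest mode's
  relaxation, and the upper edge keeps the time-averaged MSD reliable —
  its sampling error grows like $\sqrt{\tau_{max}/T_{run}}$, which is why
  the run is long rather than the window wide.  Expected fitted exponent
  from the exact mode solution: 0.74 (the asymptotic 3/4 is approached
  slowly from below; the free filament's centre-of-mass diffusion nudges
  the fit upward).
* `tensioned_filament_config()` — strong tension, negligible bending at
  all resolved wavelengths, 10 000 frames; exact-solution expectation for
  the fitted window: 0.51.
* `thermal_control_config()` / `kicked_filament_config()` — a short pinned
  tensioned filament whose slowest mode relaxes in ~8 time units, sampled
  every 20 (so backbone skewness sees effectively independent frames),
  without and with telegraph kicks at the middle bead (amplitude 3,
  mean burst 6, mean quiet interval 34 — a 15% duty cycle whose
  burst-average displacement is several thermal standard deviations).
  Thermal controls keep the flagged fraction at the nominal test level
  (≤1%); kicked filaments are detected at the forced site in ≥90% of
  replicates.

The renderer draws each contour as a line source convolved with a Gaussian
point-spread function on a constant background (so a straight tubule's
cross-section is a Gaussian of the configured width whose peak equals the
configured intensity), then applies Poisson and/or Gaussian noise.  What
the renderer does *not* emulate — out-of-focus light, neighbouring
tubules, motion blur within an exposure, detector fixed-pattern noise —
bounds what passing tests show about real data: they validate the
geometry and statistics of the measurement chain, not its robustness to
every microscopy artefact.  One physical limit surfaced by the renderer
is worth stating: blurring attenuates the apparent amplitude of contour
curvature at wavenumber $q$ by roughly $e^{-q^2\sigma^2/2}$, because the
ridge line of a blurred curved filament is displaced toward the centre of
curvature.  Tracked mode variances at wavelengths comparable to a few PSF
widths are therefore biased low by tens of percent regardless of tracker
quality; validation consequently compares the total curvature-mode energy
and the per-mode amplitude time series (correlation > 0.9), and users
should treat high-mode variances from real videos as lower bounds.

# Numerical choices and degenerate inputs

* Zero-variance displacement samples: skewness undefined, flagged, never
  significant.  Zero-variance amplitude series: sustained iff the constant
  is non-zero.
* Zero residual noise in the SNR gate: SNR = +Inf, passes (a sampled
  noiseless Gaussian leaves small smoother residuals, giving a large
  finite SNR instead).
* Repeated identical contour points are rejected at construction; the
  snake drops consecutive near-duplicates produced by border clamping.
* The persistence fit refuses fewer than 3 tubules; near-rigid data are
  flagged, not silently reported.
* All randomness is seeded; multi-stage runs derive per-stage sub-seeds
  from one master seed (`derive_seed()`), all below $2^{31}$.

# Problem sizes

The validation suite runs at desk scale by design: $10^4$ sampled chains
for persistence recovery, a 30 000-frame thermal run and a 10 000-frame
tensioned run for the exponent regimes, 1000-frame Brownian controls,
~100–200 short pinned-filament replicates for the skewness error rates,
and 100 random 50-tubule matrices for the mining equivalence — a few
minutes in total on one CPU.
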