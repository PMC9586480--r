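---
title: "Tracking and modeling traveling calcium and glutamate waves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking and modeling traveling calcium and glutamate waves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytowave)
```

## The problem

Wounding a leaf triggers two kinds of calcium waves. A *local* (and later
*distal*) wave creeps through the tissue at a few μm/s with a traveling
intensity peak that slows over time; a *vascular* wave races along the
veins at hundreds of μm/s. The mechanistic questions are kinematic: does
the slow wave advance like the front of a diffusing activator
(`r ∝ √t`), and is the fast wave consistent with xylem bulk flow carrying
an activating chemical, slightly ahead of the flow because of
shear-enhanced dispersion? `phytowave` provides the full measurement chain
needed to answer those questions from fluorescence time-lapse stacks, plus
synthetic generators so every estimator can be validated against known
ground truth.

## Models and assumptions

**Diffusive front.** For a diffusing messenger, mean squared displacement
grows linearly in time (Einstein–Smoluchowski), so a front defined by a
fixed concentration (or intensity) criterion advances as `r(t) = √(c·D·t)`.
Two fits are exposed: the free power law `r(t) = a·t^b` (nonlinear least
squares, `b` initialized at 0.8), whose fitted exponent near 0.5 is the
model-free diagnostic of diffusion, and the constrained diffusion law
`r(t) = √(6·D·t)` (initialized at `D = 60` μm²/s), which extracts the
coefficient. The factor 6 is the 3D MSD convention; it is a convention,
not a physical claim about the tissue geometry, and the same convention is
used by the generator so that recovery is exact (`fit_diffusion` returns
the generating `D` to machine precision on noiseless input).

**Bulk flow + Taylor dispersion.** In a tube of radius `a` with mean flow
speed `u`, shear spreads a solute axially with effective coefficient
`D_eff = Dm·(1 + Pe²/48)`, `Pe = u·a/Dm` (the Aris–Taylor result for
cylindrical Poiseuille flow). For a step release at the origin the
cross-section-averaged concentration is the advected error-function
profile `c(x, t) = ½·erfc((x − u·t)/(2√(D_eff·t)))`. A calcium wave
ignited wherever concentration exceeds a threshold `θ` (as a fraction of
source concentration) therefore has its front at

`x(t) = u·t + 2·√(D_eff·t)·erfc⁻¹(2θ)`.

For `θ < 0.5` the wave *leads* bulk flow by a gap growing as `√t`; at
`θ = 0.5` it coincides with it. The reference parameter set is
`u = 500 μm/s`, `Dm = 100 μm²/s` (10⁻⁶ cm²/s), `a = 10 μm`, giving
`Pe = 50` and `D_eff ≈ 5308 μm²/s`. Because the constant-flow assumption
only holds early, predictions and fits are restricted to `t ≤ 10 s` by
default (`t_limit`); beyond it the functions warn rather than refuse.

`fit_theta()` estimates `θ` from paired tracer/calcium distance–time
tracks: the tracer (e.g. HPTS, a bulk-flow marker) is summarized by a
Gaussian-process posterior mean, and `θ` minimizes the squared mismatch
between the calcium track and `GP mean + 2√(D_eff·t)·erfc⁻¹(2θ)`. Since
the dispersion term is linear in `g = erfc⁻¹(2θ)`, the optimum is a
weighted least-squares slope, solved in closed form — no iterative
optimizer, no convergence failures, and a boundary estimate is reported
with a warning. The flow speed is a stated parameter, never re-fit.

**GP regression.** Tracer kinematics are smoothed with a zero-mean
(after centring) Gaussian process with squared-exponential kernel;
hyperparameters maximize the marginal likelihood from a small
deterministic multi-start grid, and the noise variance is floored at
`1e-8` of the signal variance so noiseless data are interpolated. This
replaces an external GP dependency with ~80 lines of standard linear
algebra, tested for interpolation and for prediction of linear kinematics
to <1%.

**Paired lag test.** Whether the calcium front consistently leads the
tracer is assessed with an exact two-sided binomial sign test (smaller
tail doubled, capped at 1; ties removed and reported). The worked case of
21 positive lags out of 22 gives `p = 46/2²² ≈ 1.1 × 10⁻⁵`.

## The measurement chain

**Scanning.** Three geometries mirror the assays: equiangular radii from a
wound point (default 100), radii anchored on the circle through three
droplet/trichome edge points (sweeping the arc between the first two
points that does not contain the third, default length 700 μm), and
equidistant perpendicular transects from a vein segment (default 10 lines
of 500 μm). Lines are sampled at one-pixel steps by bilinear
interpolation; lines leaving the image are clipped and excluded from the
mean beyond their valid length, never zero-filled. Per-pixel sampling
followed by a cross-line mean was chosen over distance binning; for
rotationally symmetric inputs the two agree to interpolation error.

**Baseline and noise.** The baseline is the mean intensity of the tissue
before the response arrives (`pre_frames`). The noise band is
`baseline ± 1.96·SD̄` and the front threshold `baseline + SD̄`, where `SD̄`
is the average over time points of the SD across distance of the averaged
profile. By default *all* frames contribute to `SD̄` ("across the whole
dataset"), signal frames included. This choice matters: it places the
front threshold well above the noise floor, so the outermost-crossing
front rule is robust (on synthetic stacks with noise at 10% of the wave
amplitude, every frame tracks within 5 pixels), while the temporal
sharpness of the wave foot keeps the raised-threshold crossing within
about one pixel of the low-threshold front. The pure-noise-band reading
is available as `sd_scope = "pre_frames"`; with it, a raw-profile
outermost crossing is exact on noiseless data but degrades badly under
noise.

**Peak tracking.** Each time point's averaged profile is LOESS-smoothed
(tricube weights, local degree 2, `surface = "direct"` so smooth inputs
are reproduced exactly). Local maxima are points strictly greater than
all neighbours within `window` grid steps (default 5); boundary points are
never maxima, and exact symmetric ties are broken by a negligible
deterministic ramp, which also stops numerical wiggles on flat profiles
from qualifying. Among the maxima exceeding the upper noise band, the
selected peak maximizes intensity subject to never moving backward
(ties toward the smaller distance); time points with no qualifying
maximum stay missing and are never interpolated. The per-point
signal-to-noise ratio is peak intensity divided by the upper noise value.

**Spans.** `loess`'s conventional default span is 0.75, but a traveling
peak is a *local* feature: the span should resolve the wave, not average
over it. The tracking default is 0.3; end-to-end validation on 256-pixel
stacks (500 μm profiles, 126 samples) uses 0.1, i.e. a ~50 μm window
comparable to the wave foot. With that setting the tracked peak and front
stay within 2 pixels of the generating laws on noiseless stacks, and
within 5 pixels on >90% of frames at 10% noise. The CF peak-width module
defaults to span 0.1 for the same reason (vein ridges are ~10 px wide);
its residual SD can be supplied explicitly when the analytic crossing
level is known.

**Time zero.** Either the stimulus frame (needle contact) or the first
forward progression of the peak/front (droplet and distal assays);
entries before zero are dropped.

**Kinematic summaries.** Each replicate's distance–time track is
summarized by a degree-6 polynomial forced through the origin (times are
rescaled to [0, 1] internally — raw `t⁶` over hundreds of seconds is
numerically hostile — and coefficients mapped back, so `p(0) = 0` holds
structurally). Replicates are averaged coefficient-wise, which equals
pointwise averaging because the basis is shared; velocity is the analytic
derivative. Vascular replicates get a through-origin straight line,
`slope = Σtd/Σt²`. Group comparisons use the pooled-variance Student
*t* test per time point (Welch behind a flag) — identical groups give
`t = 0, p = 1`, and time points with fewer than two replicates per group
are skipped — and pairwise Wilcoxon rank-sum tests (exact when both
groups have ≤ 10 replicates) with Bonferroni correction for speeds.

## The synthetic world

The generators state the world the estimators are validated in; their
defaults are fixed once and not revisited:

- Acquisition: frames every 2 s, 16-bit grayscale, 256 px images at
  4 μm/px (local waves), baseline 100 a.u.
- Wave: diffusion coefficient `D = 116 μm²/s` (the glutamate-scale
  value), response amplitude 500 a.u.
- Indicator response: difference of exponentials with rise 2 s and decay
  20 s after local activation. Indicator kinetics are not part of the
  published analysis; this choice produces the observed phenomenology (a
  traveling peak behind an advancing front) and the peak law is known
  exactly: the peak trails the front by the response's peak time.
- Noise: additive i.i.d. Gaussian per pixel per frame — a deliberate
  simplification (no photon shot noise, no bleaching, no motion).
- Vascular tables: tracer at `d = u·t`, calcium at the dispersion front
  above, default `θ = 0.25`, sampled every 0.5 s to 10 s.
- All randomness flows from a single integer seed; identical parameters
  and seed give bit-identical arrays.

Two front conventions exist for image stacks. `front_mode = "sqrt"`
(default) prescribes activation at `t = r²/(6D)`, so the true front is
exactly `√(6·D·t)` — the form every downstream fit assumes.
`front_mode = "kernel"` derives activation from the 2D instantaneous
point-source kernel `M/(4πDt)·exp(−r²/4Dt)`; its threshold-crossing front
is `√(4Dt·ln(K/t))`, which is *not* a pure power law (its log–log slope
is below 0.5 and drifts with `t`). The package keeps both because the
published fits assume the first form while the microscopic release model
implies the second; validation of `√t` recovery uses "sqrt" mode, and the
kernel mode documents how far a threshold front departs from the ideal
scaling. A green recovery test therefore establishes estimator
correctness *given* the stated world — not that real wound waves are
ideal diffusion fronts, nor anything about real indicator kinetics,
bleaching or tissue heterogeneity.

The released amount per wound is unknown in the literature;
`source_mass` is a free parameter whose default is chosen so the
kernel-mode front spans the default image over the default acquisition.

## Numerical choices

- `nls` fits use the bounded `port` algorithm (`D, a > 0`) with
  `scaleOffset = 1`, so exact zero-residual data converge instead of
  erroring and noisy optimization cannot wander into negative
  coefficients.
- `erfc`/`erfc⁻¹` are computed through the normal CDF/quantile; the
  inverse was cross-checked against a bisection oracle.
- The TIFF layer implements only what the pipeline emits: uncompressed
  little-endian 16-bit grayscale, one strip per page, calibration in a
  JSON sidecar. Intensities are rounded and clamped to [0, 65535] on
  write.
- Degenerate inputs are contracts, not accidents: collinear circle
  points, coincident segment endpoints, empty pre-response regions,
  all-equal GP times, `θ` outside (0, 1) and sub-minimal point counts all
  raise errors; boundary `θ` estimates, beyond-`t_limit` predictions,
  lagging calcium and empty tracks warn.

## Known limitations

- One wave per anchor; colliding or re-entrant waves are out of scope.
- Anchors (wound point, droplet edge points, vein segments) are
  user-supplied, as in the assays; there is no automated detection.
- The dispersion front assumes constant flow speed; it is only trusted to
  `t_limit` and `u` is never estimated from data.
- The synthetic noise model is Gaussian and stationary; real acquisitions
  show bleaching trends and structured background that the baseline model
  only partially absorbs.
- The CF width module treats overlapping peaks at vein junctions as
  separate peaks per line, as the grid-line method implies.
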