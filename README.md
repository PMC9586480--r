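# phytowave

Quantitative analysis of traveling calcium and glutamate waves in plant
tissue, from fluorescence time-lapse imaging to physical transport models.

Wounded plants signal systemically: a wave of cytosolic calcium travels
outward from the wound through the leaf lamina and, much faster, along the
vasculature. The slow local/distal waves behave like the footprint of a
*diffusing* chemical messenger (an apoplastic glutamate burst activating
glutamate receptor-like channels), while the fast vascular wave rides
xylem *bulk flow*, led slightly by shear-enhanced (Taylor) dispersion of
the activating chemical. This package re-implements that analysis chain as
tested, reusable components:

- **scan** — geometric fluorescence scanning of image stacks: 100 radii
  fanning out from a wound point, radii anchored on a circle fit through
  three droplet-edge points, or 10 perpendicular transects departing from a
  vein segment; bilinear sampling at pixel steps, averaged into
  distance-time intensity profiles.
- **tracking** — baseline and noise-band estimation
  (`noise = baseline ± 1.96·SD̄`, front threshold `baseline + SD̄`), LOESS
  smoothing, local-maxima detection, and traveling-peak tracking under a
  monotone-progression rule; wave front as the outermost threshold
  crossing.
- **kinematics** — through-origin degree-6 polynomial summaries of distance
  over time, analytic velocities, through-origin vascular speed fits,
  per-time-point Student *t* tests and pairwise Wilcoxon rank-sum tests
  with Bonferroni correction.
- **transport** — nonlinear fits of the front laws `r(t) = a·t^b`
  (diffusion ⇒ `b = 1/2`, Einstein–Smoluchowski) and `r(t) = √(6·D·t)`;
  Gaussian-process regression of tracer distance–time data; the
  bulk-flow + Taylor-dispersion front
  `x(t) = u·t + 2·√(D_eff·t)·erfc⁻¹(2θ)` with
  `D_eff = Dm·(1 + Pe²/48)`, `Pe = u·a/Dm`, and channel-activation
  threshold `θ` fitted from paired tracer/calcium tracks; exact paired
  sign test for tracer-vs-calcium lags.
- **cfwidth** — symplastic-connectivity readout: mean peak width of
  carboxyfluorescein unloading around veins, measured base-to-base along a
  50 + 50 grid of scan lines.
- **synthetic** — generators for all of the above with known ground truth
  (radial and vein-perpendicular wave stacks, paired vascular
  distance–time tables, vein-ridge images), written as multi-page 16-bit
  TIFF plus CSV/JSON.
- **cli** — `run_subcommand()` plus `inst/cli/phytowave.R` wire the modules
  into `simulate`, `track-local`, `track-distal`, `vascular-speed`,
  `fit-transport` and `cf-width` runs with structured logs.

## Worked example

Simulate a wound-triggered radial wave with the glutamate-scale diffusion
coefficient (`D = 116` μm²/s), scan it with 100 radii, track peak and
front, and fit the transport models:

```r
library(phytowave)

p  <- local_wave_params(D = 116, noise_sd = 25, n_frames = 120,
                        image_size = 256, pixel_size = 4, seed = 1L)
g  <- gen_local_wave_stack(p)
ps <- scan_stack(g$stack,
                 scan_geometry("radial_point", points = p$origin,
                               n_lines = 100, line_length = 500))
bl <- estimate_baseline(ps, pre_frames = 1)
tk <- track_wave(ps, bl, span = 0.1)
head(subset(as.data.frame(tk), is.finite(peak_um)), 4)
#>   t_s peak_um peak_intensity   snr front_um
#> 4   6      28          602.7 2.061       60
#> 5   8      44          603.3 2.063       72
#> 6  10      60          605.4 2.070       80
#> 7  12      68          603.7 2.064       88

fit <- fit_power_law(data.frame(t_s = tk$t_s, distance_um = tk$front_um))
#> power-law exponent b = 0.507 +/- 0.001
dfit <- fit_diffusion(data.frame(t_s = tk$t_s, distance_um = tk$front_um))
#> diffusion coefficient D = 114.7 +/- 0.1 um^2/s
```

The tracked front advances as `√t` (`b ≈ 0.5`: diffusion-like kinematics)
and the diffusion fit recovers the generating coefficient to ~1% despite
the added noise — the two headline statistics of the wound-wave analysis,
here validated against known ground truth.

## Command line

```sh
Rscript inst/cli/phytowave.R simulate --out out/
Rscript inst/cli/phytowave.R track-local --out out/ out/local-wave.tif
```

Exit codes: 0 ok, 2 configuration error, 3 data error. See the methods
vignette (`vignettes/wave-analysis.Rmd`) for the model assumptions, the
tunable parameters and their defaults, and known limitations.
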