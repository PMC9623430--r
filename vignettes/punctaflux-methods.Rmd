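---
title: "Quantifying CP12-dependent enzyme complex formation and NAD(P)H redox dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CP12-dependent enzyme complex formation and NAD(P)H redox dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punctaflux)
```

## The measurement problem

In cyanobacteria the small redox-sensing protein CP12 sequesters two
Calvin-Benson cycle enzymes — GapDH2 (a NAD(P)H-using glyceraldehyde
3-phosphate dehydrogenase) and PRK (phosphoribulokinase) — into an inactive
ternary complex when the cell's thiol pool is oxidized, typically in
darkness. In cells expressing eYFP-tagged GapDH2 or PRK, complex formation is
visible as the fluorescence signal collapsing from a diffuse cytoplasmic
distribution into a handful of bright puncta; re-illumination disperses them
again.

punctaflux quantifies this redistribution and relates it to the cellular
redox state. Its stages are:

1. **Segmentation** of cells from the chlorophyll autofluorescence channel.
2. **Heterogeneity**: per cell and per frame, the *normalized standard
   deviation* (nsd) of the eYFP pixel intensities — the coefficient of
   variation, sd/mean. A diffuse signal gives nsd near 0; concentrating the
   same total intensity into puncta raises it.
3. **Kinetics**: monoexponential fits of nsd traces across dark (assembly)
   and light (disassembly) phases.
4. **NAD(P)H trace analysis**: the photo-reducible level and the dark
   oxidation-rate fit from saturating-pulse relaxation traces.
5. **Correlation**: the exponential dependence of nsd on actinic light
   intensity, and the linear regression of nsd on the oxidation rate.
6. **Assays**: enzyme activity from an OD340 slope (Beer-Lambert) and
   calibration-curve quantification.

Every stage is exercised against a synthetic-data module that generates
image stacks, traces and assay curves with known ground truth.

## The heterogeneity statistic

For a cell region with pixel intensities $x_1,\dots,x_n$,

$$\mathrm{nsd} = \frac{s}{\bar x}, \qquad
  s = \sqrt{\tfrac{1}{n-1}\sum_i (x_i - \bar x)^2}.$$

The sample standard deviation ($n-1$ denominator) matches common image
analysis tooling; a population-SD variant is available via
`sd_type = "population"`. The statistic is invariant under multiplying all
intensities by a positive constant (tested to 1e-12), is zero exactly when
the region is uniform, and — because the generator conserves each cell's
total eYFP intensity — is strictly increasing in the fraction of signal
bound into puncta. A zero-mean region makes the ratio undefined; it is
returned as `NA` with an explicit flag, never silently as 0. No background
subtraction is applied inside ROIs.

## Segmentation

A trained pixel classifier is replaced by a deterministic procedure:
automatic Otsu thresholding of the (max-projected) chlorophyll channel,
4-connected component labeling, and an area filter (`min_area = 50` px² by
default; the post-processing of the original classifier workflow is not
specified anywhere, so this default is our choice). The threshold is
computed on the image rescaled to [0, 1], which makes segmentation exactly
invariant to positive rescaling. Labels are assigned in raster order of each
region's first pixel. The mask is computed once per time-lapse from the max
projection and held static — cells are immobilized on agar — and touching
cells are *not* split (no watershed): on real data, abutting cells merge
into one ROI, a documented limitation. An externally produced label mask can
be imported through `labeled_mask()`/`read_mask()` for users with classifier
output.

## Transition kinetics

Per-cell nsd traces are fitted with

$$y(t) = \mathrm{plateau} + (\mathrm{baseline} - \mathrm{plateau})
          \, e^{-k (t - t_0)},$$

restricted to the dark phase (assembly) or light phase (disassembly),
$t_0$ being the first frame of the phase. The transition shape is not
specified by any mechanistic model, so the monoexponential is the simplest
form consistent with the observed curves; a model-free half time (first
crossing of the midpoint between the medians of the first and last three
points) is always reported alongside, so conclusions never rest on the
functional form. Initialization uses the first/last three points for
baseline/plateau and $k_0 = 3/\mathrm{duration}$; $k$ is bounded to
$(10^{-5}, 10]$ s$^{-1}$. Constant traces and non-positive fitted rates are
flagged rather than reported. Across cells, rates are summarized by median
and MAD, which is robust to occasional segmentation outliers.

Defaults for the simulated dynamics (`kinetic_preset()`): GapDH2
$k_\mathrm{assembly} = 0.030$ s$^{-1}$, $k_\mathrm{disassembly} = 0.06$
s$^{-1}$; PRK $k_\mathrm{assembly} = 0.012$ s$^{-1}$,
$k_\mathrm{disassembly} = 0.15$ s$^{-1}$. These encode the sequential
binding order of the ternary complex — GapDH2 is recruited first (faster
assembly) and released last (slower disassembly) — at time scales that put
complex formation within 1–2 minutes of darkness and dispersal within tens
of seconds of re-illumination, consistent with live-cell observations.

At the study conditions used in the tests (noise SD of 10% of the plateau on
the imaging time grids), the pooled median relative error of the rate over
200 simulated traces is close to the Cramér-Rao bound of the three-parameter
exponential fit (about 9-10%): the least-squares estimator is essentially
efficient here, and no re-parameterization would do better without extra
assumptions.

## NAD(P)H trace analysis

A *trigger run* is: 1 s at the actinic intensity under investigation, a
600 ms saturating pulse (3200 µmol photons m⁻² s⁻¹) that fully reduces the
NAD(P) pool, then 13.4 s of darkness during which the pool re-oxidizes —
15 s in total. Four consecutive runs are recorded; the first is treated as a
conditioning run and discarded, and runs 2-4 are averaged pointwise
(`average_replicates()`).

**Photo-reducible level.** The signal at the end of the dark period is
subtracted from the whole trace; the maximum between 1 s and 1.6 s is then
divided by the pre-pulse level. Two readings of "the level from 0 s to 1 s"
are possible; the mean over [0, 1 s) is the default and the final pre-pulse
sample is available via `prepulse_method = "endpoint"`. Likewise "the value
at the end of the dark period" defaults to the mean of the final five
samples (noise robustness) with the literal last sample behind
`dark_end_method = "last"`. The statistic is invariant to adding a constant
to the whole trace and to positive rescaling.

**Oxidation rate.** From the beginning of the dark period at 1.6 s (samples
at exactly 1.6 s included), $y(t) = c + A e^{-k(t - 1.6)}$ is fitted by
Levenberg-Marquardt least squares on a growing window: ten samples are added
per iteration, and the window stops growing once the fitted curve's absolute
slope at the window end, $A k e^{-k(t_\mathrm{end}-1.6)}$, drops below a
threshold (default $5\times10^{-8}$ signal units per second — the
instrument-native scale of this threshold is not standardized, so it is an
explicit parameter). Faster decays therefore flatten, and stop the window,
sooner. Non-decaying or constant segments are flagged, not fitted.

The trace sampling interval defaults to 0.02 s (50 Hz), a plausible rate for
slow-kinetic runs; it is a `trigger_run()` parameter.

## Light-intensity study and cross-modal regression

At each actinic intensity $I$, fixed-cell images give a per-intensity nsd
(mean over cells of per-cell nsd from max-projected stacks) and the trigger
run gives an oxidation rate. Two fits summarize the study:

* `exp_light_response()`: $\mathrm{nsd}(I) = c_0 + a e^{-bI}$ with
  $a, b > 0$, so the predicted maximum is always in complete darkness
  ($I = 0$, which is included as a data point rather than excluded).
  Monotone-increasing data contradict the model and are flagged.
* `light_series_regression()`: unweighted ordinary least squares of nsd on
  the oxidation rate, with intercept. Both axes are estimates; no
  errors-in-variables correction is applied (documented limitation).

The synthetic study (`simulate_light_study()`) couples the true bound
fraction $b(I) = 0.05 + 0.75\,e^{-0.02 I}$ to the true oxidation rate
linearly, $k(I) = 2.2 - 2.25\,b(I)$, giving rates from about 0.4 s$^{-1}$ in
darkness to about 2.1 s$^{-1}$ at 400 µmol photons m⁻² s⁻¹ — dark
re-oxidation settling within roughly 2-12 s, slower in dark-acclimated
cells, as observed in vivo. The negative coupling (more sequestered enzyme,
slower re-oxidation) is the biological default; the sign is a parameter and
its recovery by the regression is part of the test suite.

## Enzyme assay computations

`zwf_activity()` finds the most linear `window_minutes` span (largest $R^2$)
of the post-substrate OD340 segment and converts its slope via Beer-Lambert,
using $\varepsilon_{340} = 6.22$ mM$^{-1}$cm$^{-1}$ for NADPH. The effective
path length of a 200 µL microplate well is instrument-dependent; the default
is 0.56 cm and it is configurable, as are well volume and protein mass
(defaults mirror a 200 µL well loaded with 10 µg protein). Negative slopes
yield an activity of 0 with a warning. Calibration curves are fitted through
all standards without forcing the origin (colorimetric assays have nonzero
blanks); inverse predictions outside the calibrated range are returned with
an extrapolation flag.

## The synthetic-data generators

The generators emulate the statistical structure the analysis relies on, not
the optics of a microscope:

* **Cells** are non-overlapping axis-aligned ellipses (radii 8-12 px) on a
  dark canvas — real cocci imaged at 63× are round; the ellipse is cosmetic.
  Placement is rejection sampling with bounded retries (an error if the
  field cannot hold the requested cells).
* **eYFP partitioning**: each cell carries a fixed total intensity; a
  fraction `bound_fraction` is split across 1-5 Gaussian puncta (σ = 1.5 px,
  kernels normalized over the cell's own pixels, emulating
  diffraction-limited spots — the observed spot counts resemble the one to
  five carboxysomes typical of these cells, and the count is exposed as
  `spots_per_cell` rather than fixed), the remainder is spread evenly. Total
  intensity is conserved across bound fractions to machine precision, which
  is what makes nsd strictly monotone in the bound fraction.
* **Dynamics** are first order: $b(t) = 1 - e^{-k_a t}$ in darkness,
  exponential decay after the light switch. Geometry is drawn once and held
  fixed across frames.
* **Noise** is additive Gaussian clipped at zero. Poisson shot noise would
  be more faithful to a photon-counting detector but is left unimplemented;
  at the moderate noise levels studied the difference is immaterial for the
  statistics tested.
* **Timing**: darkness is imaged every 10 s for 300 s (31 frames at t = 0,
  10, ..., 300) and light every 0.47 s for 30 s (64 frames). Because frame
  times must be strictly increasing, the light sequence starts one interval
  after the switch (t = 300.47, ...). NAD(P)H traces follow the trigger-run
  grid exactly.
* **Seeds are mandatory** everywhere; generators save and restore the
  caller's RNG state, so identical calls are bit-identical and nothing
  consumes global randomness.

What passing tests on these data do **not** show: robustness to focus drift,
photobleaching, cell motion, touching cells, or non-Gaussian detector noise.
The generators are a correctness harness for the estimators, not a
microscope simulator.

## Numerical choices

* All nonlinear fits use Levenberg-Marquardt (`minpack.lm::nls.lm` directly,
  which is robust to the zero-residual fits that arise on noiseless data).
* Degenerate inputs (constant traces, zero means, flat responses,
  non-decaying segments) are flagged via `converged = FALSE` or `NA` with a
  warning — never silently coerced to a number.
* Problem sizes in the test suite: fields of 5-20 cells on 96-512 px
  canvases, 100-200 simulated traces per recovery check, and 50 seeded
  light studies of 6 intensities × 20 cells × 4 replicates; these sizes give
  stable medians while keeping the default test run fast.
* Image stacks are stored as 32-bit float TIFF, rescaled to [0, 1] by the
  stack maximum with the factor recorded in the JSON sidecar; round trips
  are exact to single precision for images and exact for label masks
  (16-bit) and all CSV/JSON artifacts.

## Worked example

```{r example, eval = FALSE}
# a dark/light time-lapse with the GapDH2 preset
preset <- kinetic_preset("gapdh2")
tl <- simulate_timelapse(k_assembly = preset$k_assembly,
                         k_disassembly = preset$k_disassembly,
                         n_cells = 10, noise_sd = 0.05, seed = 42,
                         image_shape = c(192, 192))
mask <- segment_cells(max_project(tl$stack, "chlorophyll"))
het <- heterogeneity_series(tl$stack, mask)
fit_transitions(het, "assembly")

# NAD(P)H side
sim <- simulate_nadph_trace(oxidation_rate = 0.5, noise_sd = 0.02, seed = 43)
analyze_nadph_run(sim$traces)$oxidation

# or everything at once, from the bundled configuration
cfg <- system.file("extdata", "demo_config.yaml", package = "punctaflux")
res <- run_pipeline(cfg, out_dir = tempfile())
res$fits$linear
```

## Known limitations

* Touching cells merge into one ROI (no watershed splitting).
* The monoexponential is a summary model, not a mechanistic multi-state
  binding model; the model-free half time is the hedge.
* The nsd-on-rate regression ignores uncertainty in the abscissa.
* NADH and NADPH contributions to the fluorescence signal are not
  deconvolved; the oxidation rate describes the pooled signal.
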