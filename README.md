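# punctaflux

Quantifying in vivo protein-complex assembly from fluorescence heterogeneity
and NAD(P)H redox kinetics.

## What it is for

In cyanobacteria, the redox-sensing protein CP12 switches the Calvin-Benson
cycle off in darkness by sequestering two of its enzymes, GapDH2 and PRK,
into an inactive ternary complex. In cells expressing eYFP-tagged enzyme,
complex formation shows up under the microscope as the diffuse fluorescence
collapsing into a few bright puncta. punctaflux is an analysis toolkit for
experiments built on that readout:

* **Per-cell heterogeneity traces.** Cells are segmented from the
  chlorophyll channel (Otsu threshold, 4-connected components, area filter),
  and for every cell and frame the *normalized standard deviation*
  (nsd = sd/mean of the eYFP pixels — the coefficient of variation) is
  computed. Diffuse signal: nsd ≈ 0; punctate signal: high nsd.
* **Assembly/disassembly kinetics.** Monoexponential fits
  `y(t) = plateau + (baseline − plateau)·exp(−k(t − t0))` to the dark- and
  light-phase nsd traces, per cell, summarized by median ± MAD, with a
  model-free half time reported alongside.
* **NAD(P)H relaxation analysis.** From saturating-pulse trigger runs
  (1 s actinic + 0.6 s pulse + 13.4 s dark): replicate averaging (first run
  discarded), the photo-reducible level (dark-end-subtracted pulse maximum
  over pre-pulse level), and the dark oxidation rate from an exponential fit
  whose window grows until the fitted slope falls below 5e-8 signal units/s.
* **Cross-modal regressions.** nsd(I) = c0 + a·exp(−b·I) across actinic
  intensities, and ordinary least squares of nsd against the oxidation rate.
* **Assay helpers.** Glucose 6-phosphate dehydrogenase (Zwf) activity from
  the OD340 slope via Beer-Lambert, and calibration-curve quantification.
* **A synthetic-data module** that generates image stacks, NAD(P)H traces
  and assay traces with ground truth attached, so every estimator is
  testable end to end without a microscope.

See `vignettes/punctaflux-methods.Rmd` for the models, parameter choices and
limitations.

## Worked example

```r
library(punctaflux)

preset <- kinetic_preset("gapdh2")
tl <- simulate_timelapse(k_assembly = preset$k_assembly,
                         k_disassembly = preset$k_disassembly,
                         n_cells = 5, seed = 2, image_shape = c(160, 160))
mask <- segment_cells(max_project(tl$stack, "chlorophyll"))
mask
#> <labeled_mask> 160 x 160 px, 5 cell(s)

het <- heterogeneity_series(tl$stack, mask)
fit_transitions(het, "assembly")
#> <transition_fits> assembly: 5/5 cells converged
#>   rate median = 0.03 /s (MAD 7.86e-11), t1/2 median = 23.1 s

sim <- simulate_nadph_trace(oxidation_rate = 2, noise_sd = 0, seed = 3)
oxidation_rate(average_replicates(sim$traces))
#> <oxidation_fit> rate = 2 /s, amplitude = 1.5, offset = 1.5
#>   fit window ends at 10.580 s (450 samples), rmse = 0
```

On this noiseless time-lapse the fitted assembly rate equals the generator's
0.03 s⁻¹ exactly (half time ln 2/0.03 ≈ 23.1 s), and the NAD(P)H fit
recovers the true oxidation rate of 2 s⁻¹; the adaptive window stops at
10.58 s, where the fitted exponential's slope has fallen below the 5e-8
threshold. The full pipeline (simulate → segment → heterogeneity → kinetics,
NAD(P)H analysis, light-intensity study and regressions, with all artifacts
written to disk) runs from a YAML configuration:

```r
cfg <- system.file("extdata", "demo_config.yaml", package = "punctaflux")
res <- run_pipeline(cfg, out_dir = "demo_out")
res$fits$linear
#> <light_linear_fit> nsd = 1.982 + -0.8954 * rate, r^2 = 0.9969, n = 6
```

The negative slope is the expected biology: the more enzyme is bound into
complexes (high nsd, dark-acclimated cells), the slower the NAD(P)H pool
re-oxidizes.

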