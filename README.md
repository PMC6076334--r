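# smiauto

Computational toolkit for **automated in-cell single-molecule imaging**:
the full software chain that turns raw TIRF microscopy movies into
biophysical and pharmacological numbers, exercised end-to-end on a built-in
synthetic microscopy simulator with exported ground truth.

Automated single-molecule experiments need three things a human expert
normally provides: finding the focal plane to sub-wavelength precision,
choosing cells whose fluorescent-spot density suits single-molecule
tracking (1–3 spots/µm²), and statistically reducing hundreds of thousands
of trajectories. smiauto implements each stage for R users:

- **Autofocus** — a coarse pass where a small encoder–decoder network
  classifies bright-field iris images as in/out of focus (750 µm range,
  2.5 µm steps, stop when the evaluation value exceeds 0.5), then a fine
  pass maximizing the iris-edge sharpness
  `E = N(I_max1)·N(I_max2)/N(I_min)²` computed from a 512-bin brightness
  histogram of 21×21 edge windows, with a Gaussian fit over a 2200-a.u.
  (≈3.5 µm) feedback-axis scan in 20-a.u. (≈32 nm) steps.
- **Cell search** — the same 3-convolution/3-deconvolution network
  (sigmoid output; trained with Adam; evaluated by the average residual
  square, ARS) segments suitable-density regions in fluorescence snapshots
  and true cell regions in reflection-contrast (SRIC) images; targets
  across a 15×15 tile scan are ranked by region area.
- **Detection & tracking** — Pearson-normalized cross-correlation against
  an 11×11 Gaussian template (σ = 2 px), threshold 0.25, sub-pixel
  Gaussian-plus-plane fits (Levenberg–Marquardt), greedy shortest-first
  linking below 6 px, trajectory filters (cell mask, fitted width in
  [1.5, 2.5] px), and dual-colour similarity registration on fiducials.
- **Statistics** — MSD curves `MSD(nδt)` pooled over tracks and start
  frames; confined-diffusion MLE
  `MSD(t) = (C²/3)(1 − e^{−12Dt/C²})` across cells under normal or
  log-normal error models (per-lag scales profiled in closed form);
  diffusion-state mixtures
  `P(r) = Σ C_n r/(2D_nδt) e^{−r²/4D_nδt}` with the state count chosen by
  AIC (`k = 2N−1`, N = 1..4); oligomer-size mixtures
  `P(x) = Σ C_n N(x; nμ, nσ²)` up to 10-mers with global μ, σ; Hill
  dose–response `MSD = MSD_max − (MSD_max−MSD_min)/(1+(EC50/[L])^h)` and
  noncompetitive inhibition
  `MSD = MSD_max − (MSD_max−MSD_min)/((1+EC50/[L])(1+[I]/IC50))`, both by
  MLE with per-condition nuisance scales and profile-likelihood CIs;
  residence times and 40-s time-course binning.
- **Simulator** — multi-state / confined 2-D diffusion at 33 ms frames,
  Gaussian PSF rendering with n-mer intensities (mean nμ, variance nσ²),
  Poisson + read noise, defocus-blurred iris stacks, textured SRIC cell
  scenes with pixel-exact masks, and log-normally scattered per-cell
  dose–response tables — all seeded and bit-reproducible.

## Worked example

Simulate a two-condition experiment (resting vs stimulated receptor
mobility), track the movies, and fit the statistics:

```r
library(smiauto)

cfg <- sim_config(field_size = c(64, 64))          # 0.1 um/px, 33 ms frames
stacks <- list(); manifest <- NULL
for (i in 1:4) {
  D <- if (i <= 2) 0.12 else 0.03                  # um^2/s
  sim <- simulate_trajectories(5, 45, data.frame(D = D, fraction = 1),
                               config = cfg, seed = 60 + i)
  stacks[[sprintf("m%d.tif", i)]] <- render_movie(sim$tracks, 1L, cfg,
                                                  seed = 60 + i)$stack
  manifest <- rbind(manifest,
    data.frame(path = sprintf("m%d.tif", i), cell = i,
               condition = if (i <= 2) "mock" else "egf"))
}
run <- run_pipeline(manifest, "run1", config = cfg, stacks = stacks, seed = 2)
run$cells[, c("cell", "condition", "n_tracks", "success", "msd_66ms")]
#>   cell condition n_tracks success    msd_66ms
#> 1    1      mock       31    TRUE 0.030922664
#> 2    2      mock       39    TRUE 0.027191645
#> 3    3       egf       33    TRUE 0.009247586
#> 4    4       egf       36    TRUE 0.015299635
```

Every cell passed the success criterion (at least one trajectory longer
than 1 s), and the stimulated ("egf") cells show the expected drop of the
MSD at Δt = 66 ms — from ≈0.029 µm² to ≈0.012 µm², i.e. slower, more
confined receptor motion. `pipeline_report("run1")` writes a plain-text
summary and MSD figures.

Fitting the confined-diffusion model across 100 simulated cells
(true D = 0.05 µm²/s, C = 0.264 µm, log-normal cell-to-cell scatter):

```r
d <- simulate_confined_curves(100, D = 0.05, C = 0.264, sigma = 0.2, seed = 3)
fit_confined(d, seed = 4)
#> <confined_fit> D = 0.0503 um^2/s, C = 0.2628 um (lognormal error model;
#>                logL norm 6357.13 / log 6393.47; 100 cells)
```

Both parameters are recovered within 1%, and the log-normal error model is
correctly preferred (larger log-likelihood). See the methods vignette
(`vignettes/smiauto-methods.Rmd`) for every model, default and numerical
decision.

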