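---
title: "Models and methods behind smiauto"
author: "smiauto authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smiauto}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

smiauto reimplements, on files and simulations instead of hardware, the
computational chain of an automated live-cell single-molecule TIRF imaging
workflow: autofocus scoring, deep-learning cell search, spot detection and
tracking, and the maximum-likelihood statistics that turn trajectories into
biophysical and pharmacological parameters. This vignette documents the
models, the defaults and why they were chosen, the numerical decisions, and
what the simulator does and does not emulate.

## The synthetic microscopy simulator

Because no experimental dataset ships with the package, every analysis stage
is exercised against a simulator whose ground truth is exported alongside
its outputs.

**Trajectories.** `simulate_trajectories()` draws 2-D random walks at the
camera frame interval (default 33 ms). Each track is assigned one diffusive
state from a static mixture `(D_n, C_n)`; per frame each coordinate moves by
a normal step of variance `2 D dt`, so the expected squared step of the x/y
pair is `4 D dt`. Confinement is modelled as a reflecting square of side `C`
placed in the field; the track's start position is drawn *uniformly inside
the box*. The uniform (stationary) initial occupancy matters: it is what
makes the ensemble MSD saturate at `C^2/3`, the plateau of the confinement
model fitted later. Starting every walker at the box centre would halve the
plateau and silently bias the confinement fit. An optional per-frame state
redraw (`switch_prob`) provides Markov switching; it is off by default
because the statistics layer assumes a static mixture.

**Rendering.** `render_movie()` draws each emitter as a symmetric Gaussian
point-spread function of width 2 px (the value used by the detection
template) with a peak amplitude drawn once per track from
`N(n mu, n sigma^2)` for an `n`-mer, on a planar background with optional
incline, then applies Poisson shot noise plus additive Gaussian read noise.
This "Poisson + read noise" model is EMCCD-like without modelling the EM
gain register explicitly; vectorial PSF optics, the evanescent-field depth
profile and photobleaching are deliberately out of scope. The default pixel
size is 0.1 um/px, a typical EMCCD + 60x TIRF value; every physical
quantity is derived from the configuration, never hard-coded.

**Iris scenes.** `render_iris()` produces the bright-field iris view used
for autofocus: a bright disk on a dark surround whose edge blur grows
linearly with defocus (`blur0 + blur_rate |z - focus|` px, capped at a
quarter of the image side). That monotone blur is the only optical property
the autofocus procedures rely on. Noise is a deterministic function of
`(seed, z)` so a simulated stage revisiting a position sees the identical
image.

**SRIC cell scenes.** `simulate_sric_scene()` places non-overlapping
textured ellipses (semi-axes about 1/12 to 1/6 of the frame) on a smoothly
structured background, with the exact rasterized mask as segmentation
ground truth. The interior contrast (600 a.u. over a ~1200 a.u. background,
with moderate texture) is chosen so that adherent cells are unambiguous to
a human observer, as they are in a real reflection-contrast search
snapshot; the open question of how far a small network generalizes to
marginal, low-contrast cells is not probed by these tests.

**Dose-response tables.** `simulate_response_tables()` scatters per-cell
MSD values log-normally around the Hill or noncompetitive-inhibition curve
using the median convention `log d ~ N(log MSD - sigma^2/2, sigma^2)`, so
that the *mean* of the cell values equals the model curve — the same
convention the fitting likelihoods use.

What the simulator does **not** emulate: optical aberrations, spectral
bleed-through, photobleaching and blinking kinetics, stage drift, cell
movement and morphology changes during acquisition, and debris outside
cells. Tests passing on these simulations therefore demonstrate the
correctness of the algorithms under their own model assumptions, not
instrument-grade performance on real data.

## The encoder-decoder network

Both the coarse autofocus classifier and the cell-search/cell-region
segmentation share one architecture: three convolution stages (3x3 kernels,
stride 2, ReLU) that halve the resolution three times, mirrored by three
deconvolution stages (2x nearest-neighbour upsampling followed by a 3x3
stride-1 convolution), ending in a sigmoid so each output pixel is a
probability. Channel widths default to 8/16/32 — the smallest configuration
that trains on a single CPU in minutes. Kernel sizes, strides and widths
are not dictated by the architecture's 3+3 structure, so they are exposed
(`nn_new(channels=, strides=)`); a stride-(2,2,1) variant was evaluated for
sharper segmentation boundaries and rejected because the reduced receptive
field hurt more than the finer bottleneck helped.

Training is mini-batch Adam (defaults `lr = 1e-3`, `beta = (0.9, 0.999)`)
on the mean squared error between output map and binary target — the
quantity whose root is the evaluation metric ARS
(`sqrt(mean((y - d)^2))` over the grid; the normalizer generalizes from the
512x512 case to any input size). Binary cross-entropy is available behind a
flag but is not the default: with ~15% foreground and the small network it
converges to the background class much more slowly than the squared loss.
Gradients are exact (verified against finite differences in the test
suite), shuffling is seeded, and two runs with the same seed are
bit-identical. Networks serialize to a single binary settings file
(architecture plus weights) via `nn_save()`/`nn_load()`.

`cross_validate_training_size()` re-trains fresh networks at increasing
training-set sizes and reports the train/test ARS gap; the size where the
gap flattens indicates sufficient data, mirroring the protocol that led to
the 400/40/200 image requirements for focus classification, cell search and
cell-region detection respectively.

## Autofocus

**Sharpness score.** The high-precision focus signal is computed from the
lower half of the iris image: Otsu binarization (exhaustive
between-class-variance maximization over all candidate bin boundaries —
this definition is shared with the histogram split below and matches a
brute-force scan exactly), then a 21x21 px window per horizontal band is
shifted downward until its white fraction first drops to 50% or less,
locating the edge. The brightness histogram of all edge windows (512 bins
spanning the min-max range, which makes the score invariant under affine
intensity rescaling) is split at its Otsu boundary, each side smoothed with
a 20-bin moving average (windows shrink at the ends), and the score is
`E = N(peak1) N(peak2) / N(valley)^2` with the valley taken as the smoothed
minimum strictly between the two peak positions. `E > 1` indicates a sharp
edge; an empty valley yields an `Inf` sentinel, which occurs only on
noise-free synthetic images.

**Two-step procedure.** The coarse pass scans 750 um in 2.5 um steps,
stopping at the first position whose classifier evaluation value (the
spatial mean of the output probability map — the scalar reduction is our
choice, as the original evaluation value is not formally defined) exceeds
0.5; the classifier is trained with label 1 inside a +-4 um slab around
focus. The fine pass scans a PFS-like feedback axis: 2200 arbitrary units
covering 3.5 um in 20 a.u. (~32 nm) steps, computes `E` at each position,
fits a Gaussian to the profile (Levenberg-Marquardt; argmax fallback,
flagged) and adds a configurable calibration offset (default 0). Two
window-placement details are ours: because the ascending coarse scan stops
at the *lower edge* of the in-focus slab, the fine window is centred 2 um
(half the slab) above the coarse stop; and if the fitted peak lands within
15% of the window border the scan recentres once on the peak. On the
simulator this yields a mean final error of ~30 nm, and 100/100 simulated
trials terminate inside the +-4 um slab.

## Cell search

The fluorescence-channel network is trained on snapshots whose target mask
marks regions of suitable single-molecule density (1-3 spots/um^2; our
training masks come from the simulator's density ground truth rather than
hand painting), including slightly defocused examples so scanning
snapshots need not be refocused. The SRIC-channel network marks true cell
regions, excluding off-cell areas where fluorescent debris would
contaminate tracking. Probability maps are cut at 0.5 and connected
components below a configurable minimum area (default 64 px, a cell-scale
blob) are discarded as specks. Targets across the 15x15 tile scan are
ranked by descending region area, ties broken by raster scan order then
label, and the stage position of each target is the region centroid.

## Spot detection and tracking

Detection computes the Pearson-normalized cross-correlation between each
frame and an 11x11 Gaussian template (sigma 2 px) at every interior pixel;
the implementation is two-pass (window means first, then centred products)
and agrees with the brute-force double loop to better than 1e-10. Windows
of zero variance are defined to correlate at 0; borders are `NA`. The map
is thresholded at 0.25 — the printed working point between missing dim
spots (threshold near 1) and counting noise (near 0) — and connected
components give candidate centroids; components smaller than 4 px are
discarded, since a true diffraction-limited spot exceeds the threshold over
tens of contiguous pixels while shot-noise exceedances rarely span more
than 1-3. Each candidate is refined by a
Levenberg-Marquardt least-squares fit of a symmetric Gaussian plus an
inclined plane (7 parameters: peak, sub-pixel centre, width, two background
slopes, offset) on the 11x11 region of interest; candidates within 5 px of
the border are dropped and counted rather than fitted on a clipped window.
The low-level `nls.lm` interface is used because the formula-based wrapper
rejects the zero-residual fits that arise on noiseless synthetic frames.

Linking lists all pairs of spots in consecutive frames closer than 6 px and
accepts them greedily in ascending distance, one link per spot — the
"shortest connection first" reading; ties break by spot order. An
exhaustive maximum-cardinality minimum-total-distance matcher is included
as a reference implementation; the greedy result provably coincides with it
whenever frame-to-frame displacements are below half the nearest-neighbour
spot separation, and the test suite checks that regime explicitly. There is
no gap closing: a missed detection terminates the track. Trajectories are
then filtered: any spot outside the cell mask removes the track, as does a
mean fitted width outside [1.5, 2.5] px (per-spot filtering is available
behind a flag; the mean is the default because single-frame width estimates
are noisy). Pixel coordinates are 0-based with pixel centres at integers;
conversion to micrometres happens once, at the statistics boundary.

Dual-colour registration fits a similarity transform (translation,
rotation, isotropic scale — the closed-form complex least-squares solution)
from matched fiducial positions, with a full affine option; the residual
RMS on the fiducials is always reported.

## Statistics

**MSD and step diffusion.** The MSD pools squared displacements over all
tracks and all overlapping start frames, each displacement counting once;
per-cell curves are computed per cell and averaged at the cell level
(mean +- SE between cells), not pooled across cells. The per-molecule
diffusion coefficient is `D = dr^2 / (4T)` from two-frame displacements
(`T = 66` ms, overlapping windows).

**Confined diffusion.** Per-cell MSD curves at lags `j/30` s, `j = 1..15`,
are fitted with `MSD(t) = (C^2/3)(1 - exp(-12 D t / C^2))` by maximum
likelihood under two cell-to-cell error models: normal, and log-normal with
the `-sigma^2/2` median shift. The per-lag scales have closed-form profile
maxima — `sigma_j^2 = mean((d - m)^2)` for the normal model and
`sigma_j^2 = 2(sqrt(1 + mean(e^2)) - 1)` with `e = log d - log m` for the
log-normal one (the stationary point of the shifted likelihood) — so the
outer optimization runs over `(log D, log C)` only, from a moment-based
start plus seeded random restarts (Nelder-Mead then BFGS, tolerance 1e-10).
Profiling changes nothing about the maximum but makes a 17-parameter
problem a 2-parameter one. Both likelihoods are reported and the larger one
is adopted; on log-normally scattered cells the log-normal model wins, as
it should.

**Diffusion-state mixtures.** Displacements at 66 ms follow a mixture of
Rayleigh-type densities `C_n r/(2 D_n dt) exp(-r^2/(4 D_n dt))`.
Equivalently the squared displacements are exponential within each state,
so the MLE is computed by expectation-maximization with closed-form
M-steps, quantile-spread initialization and seeded restarts — the same
maximum as a quasi-Newton search on the stated objective, found much more
robustly. States whose rates collapse (relative difference below 1e-6) are
merged with a warning. Model selection fits `N = 1..4` and takes the
smallest `AIC = -2 logL + 2k` with `k = 2N - 1` free parameters (N
diffusion constants plus N fractions constrained to sum to one).

**Oligomer sizes.** First-frame spot intensities follow
`P(x) = sum_n C_n N(x; n mu, n sigma^2)` up to `N = 10`, with `mu` and
`sigma` global across conditions (the fluorophore does not change between
conditions) and fractions per condition. EM again has closed forms:
`mu = sum(w x)/sum(w n)` and `sigma^2 = sum(w (x - n mu)^2 / n)/sum(w)`.
This model carries a near-exact relabelling degeneracy — halving `mu`
re-expresses every `n`-mer as a `2n`-mer with almost identical likelihood —
so initialization uses the dominant intensity mode, restarts stay within
+-20% of it, and likelihood ties are broken toward the larger `mu`. The
mean cluster size is `sum(n C_n)`.

**Pharmacology.** The MSD at 66 ms versus ligand concentration is fitted
with the Hill form (upper/lower plateaus, EC50, coefficient `h`; the
zero-concentration condition sits exactly at the upper plateau) and, for
ligand x inhibitor grids, with the noncompetitive-inhibition surface
(EC50, IC50; the inhibitor-free row reduces exactly to the Hill curve with
`h = 1`). Both use one nuisance scale per condition, profiled in closed
form exactly as above, under both error models; constraints
(`MSD_max >= MSD_min`, positive EC50/IC50/h) are enforced by an
unconstrained log/span reparameterization. `dose_profile_ci()` provides
profile-likelihood intervals with log-linear interpolation of the cutoff
crossing. One calibration caveat is documented deliberately: at the
experimental scale of the inhibition assay (36 conditions x 3 cells, hence
36 free scales), the 95% profile interval is anti-conservative (~70-80%
measured coverage over replicates). The recovery tests therefore assert
majority coverage plus median-MLE accuracy over five fixed replicate
draws, rather than pretending a single draw's interval is calibrated.

**Residence time and time courses.** The residence time is the mean of
`(length - 1) dt` over tracks. `timecourse()` re-computes the estimators
in 40-s bins of track start time, flags bins ending before the stimulation
time as baseline, and omits (and reports) empty bins; the state count is
held fixed across bins so fractions remain comparable. Per-cell shift
tests use two-sided Welch t-tests with a 0.005 flag threshold — the
underlying publication-style test is not specified anywhere, so this is an
interpretation, stated as such.

**Cell success.** A recorded cell enters the statistics only if at least
one trajectory exceeds 1 s — the criterion that excluded 9 of 600 cells in
the motivating experiment — and excluded cells are counted in the pipeline
logs.

## Problem sizes and determinism

All stochastic tests run under fixed seeds. The test suite uses deliberately
modest problem sizes chosen to give the assertions adequate power: 1e4-1e5
displacements for estimator bias, 100 cells for the confined fit, 1e4 spots
for mixture fractions, 10 concentrations x 18 cells for the Hill fit, a 6x6
grid x 3 cells for inhibition (the experimental design sizes), 24-40
training images per network at 32-128 px resolution, and 100 autofocus
trials. The same sizes are used by `scripts/acceptance.R`, which recomputes
the sharpness score, the untrained-network ARS level and the autofocus
success count from scratch.

## Known limitations

- The networks are intentionally small and CPU-trainable; they segment the
  simulator's scenes well but are not expected to transfer to real
  micrographs without retraining.
- The tracker links consecutive frames only; blinking fluorophores
  fragment into multiple tracks, which biases residence times downward on
  real data.
- Mixture model selection by AIC inherits AIC's tendency to overfit at
  very large sample sizes; the displacement mixture is capped at four
  states by design.
- The inhibition-surface profile CIs are anti-conservative at three cells
  per condition (see above); more cells per condition, not a different
  formula, is the remedy.
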