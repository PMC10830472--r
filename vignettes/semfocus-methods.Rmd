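---
title: "Learned aberration correction on a virtual SEM: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learned aberration correction on a virtual SEM: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(semfocus)
```

## The problem

Automated scanning electron microscopy must keep images sharp over millions
of acquisitions without human intervention. Three instrument controls govern
the beam spot at the specimen: the working distance (wd, in micrometres of
deviation from the sharp setting) and two stigmators (stig x on-axis, stig y
diagonal, in instrument arbitrary units). A deviation
`F = (f_wd, f_stigx, f_stigy)` from the sharp baseline blurs the image —
isotropically for pure defocus, directionally for astigmatism — and the task
of an autofocus algorithm is to infer the correction `ΔF ≈ -F` quickly, from
as little electron dose as possible.

semfocus implements a two-image (phase-diversity) learned corrector: two
images are acquired at a known symmetric working-distance perturbation
`±σ_wd` around the current state, patch pairs are cropped from them, and a
convolutional regressor maps each normalized patch pair to a correction
estimate. A single image cannot disambiguate the defocus sign; the ordered
perturbed pair can. Estimates from several patch pairs are reduced to one
correction (plain mean, or a learned score-weighted mean), the correction is
applied, and the loop repeats. A second, direction-free model (a sharpness
score) turns classical simplex optimization into a slower but
instrument-independent autofocus that is used to generate labeled data for
recalibrating the fast corrector on a modified instrument.

Because a physical microscope is not required for any of the algorithmic
content, the package ships a virtual scope: a forward model of image
formation under defocus and astigmatism with dose-dependent shot noise.
Every stage — ground-truth generation, training, closed-loop control,
recalibration — runs end to end against it.

## The virtual microscope

### Beam-spot model

The point-spread function is an anisotropic Gaussian with two line foci.
With stigmator magnitude `a = sqrt(stig_x^2 + stig_y^2)` and orientation
`θ = atan2(stig_y, stig_x) / 2`, the principal-axis widths are

```
σ_u = σ0 + |k_d · wd + k_s · a|
σ_v = σ0 + |k_d · wd − k_s · a|
```

truncated at 4σ and normalized to unit sum (`beam_spot_kernel()`). This
reproduces the qualitative optics that matter for the estimation problem:

* pure defocus blurs isotropically and identically for `±wd`;
* astigmatism makes blur direction-dependent, and the sharp axis flips with
  the defocus sign (`k_d·wd = k_s·a` gives a line focus);
* rotating the stigmator vector by `φ` rotates the blur axes by `φ/2`;
* zero aberration is the unique sharpness optimum.

Two properties of this model are worth knowing because they shape the
experiments below. First, *pure astigmatism at perfect focus blurs
isotropically* (the two widths coincide at `wd = 0`), so stigmation is only
observable in combination with defocus — which the `±σ_wd` perturbed pair
always provides. Second, *flipping the sign of the working-distance
response produces exactly the 90°-rotated kernel* (`σ_u` and `σ_v` swap),
so a hypothetical instrument with both a reversed wd response and a 90°
scan rotation would be observationally identical to the unmodified one.
The modified-instrument experiments therefore use the 90° scan rotation
alone (see *Recalibration*).

Defaults are `σ0 = 0.6 px`, `k_d = 0.5 px/µm`, `k_s = 0.5 px/a.u.`, chosen
once so that the `±20 µm / ±5 a.u.` training ranges produce strong but
recoverable blur at the desk image scale.

### Noise model and dose

Acquisition (`acquire()`) convolves the scene with the beam-spot kernel,
converts intensity to expected electron counts
(`dose_per_dwell · dwell_time · I/255`), draws Poisson counts, adds
Gaussian read noise (2 gray levels by default) and rescales to 8-bit gray
levels. With `dose_per_dwell = 10` electrons/pixel/ns and 10 nm pixels, a
50 ns dwell corresponds to ≈5 electrons/nm² (visibly noisy) and 200 ns to
≈20 electrons/nm² — the low- and standard-dose regimes of the closed-loop
experiments. Shot-noise variance scales linearly with dose, so the
50 ns : 800 ns pixel-variance ratio is 16, which the tests verify by
sampling statistics.

### Scenes

`scene_raster()` generates periodic band-pass-filtered Gaussian random
fields (passband 0.05–0.45 of the sampling frequency) standing in for
stained-tissue texture, plus randomly placed smooth ellipses of
near-uniform intensity emulating blank, low-contrast regions such as
resin-filled blood vessels. The ellipse area fraction is configurable:
0.1 by default, 0.3 for the low-contrast robustness experiments.
Because the texture is periodic, FFT-based circular convolution is exact
and free of boundary artefacts.

What the simulator does *not* emulate: charging, stage drift, detector
nonlinearity, depth structure, or sample-specific texture statistics.
Passing the closed-loop tests here demonstrates the correctness and
self-consistency of the method, not its performance on any physical
instrument.

## Model architectures

All stacked models share a block design: valid convolution → batch
normalization → ReLU → max-pool → dropout (p = 0.1), with the two images
of a pair processed by the same weights (they ride along the batch
dimension and are concatenated only at the flatten stage). Pooling uses
floor division, which is required to reproduce the published head sizes
(e.g. 253 → 126). The final layer is linear.

`conv_stack_feature_dim()` applies the layer-size arithmetic
`side → floor((side − kernel + 1)/pool)` and reproduces every printed
first-FC input size from the layer tables alone: 6860 (512 px pairs),
3500 (384), 1260 (256), 140 (128), and 2520 for the score model at 512 px —
the latter only at depth 1, which is why the sharpness model consumes a
single image.

Four variants are provided:

* **plain** (`build_correction_model(..., outputs = 3)`) — seven conv
  layers (kernels 5,5,4,4,2,1,1; channels 20→70) plus a three-layer FC
  head; maps a patch pair to `(Δwd, Δstig_x, Δstig_y)`.
* **patch-score** (`outputs = 4`) — same trunk, one extra unnormalized
  score output `s_i` per patch pair; multiple predictions are reduced by a
  softmax-weighted mean (`weighted_correction()`), so uninformative
  patches can be down-weighted without any extra labels.
* **pixel-score** (`build_pixel_score_model()`) — a three-level planar
  U-Net (32 start filters, same-padding, group normalization,
  nearest-resize + convolution upsampling) whose two per-image outputs are
  concatenated and projected 64 → 20 → 4 channels per pixel: three
  correction components and one score; the dense prediction is reduced by
  a softmax-weighted spatial average.
* **sharpness score** (`build_deepscore_model()`) — six 3×3 conv layers and an
  FC head to two outputs per single image: the working-distance magnitude
  score `s_wd` and the stigmation magnitude score `s_stig`.

The engine behind these (im2col convolutions with BLAS products, exact
adjoint backward passes, AdamW) is part of the package; its gradients are
property-tested and were verified against central finite differences
during development.

Because the seven-layer chain collapses below 128 px inputs, the
desk-scale experiments use shortened four-layer variants of the same block
design (`desk_conv_spec()`, `desk_score_spec()`) for 64 px patches. Their
channel counts and heads are package design choices, sized to train in
minutes on one CPU core.

## Training

`train_model()` implements the shared protocol: per step, draw a batch of
samples, crop shared-offset patch pairs, augment the two images of each
pair independently, rescale `[0,255] → [−1,1]` (`v/127.5 − 1`), and take
an AdamW step under a step learning-rate schedule (factor 0.99 every 2000
steps). Losses:

* plain: unweighted L1 over the three components (the wd and stigmator
  ranges are close enough that no per-component weighting is used);
* patch-score: the composite loss
  `L = (1−α)·L1(weighted final, target) + α·mean_i L1(individual_i, target)`
  with α = 0.25, over 5 patch pairs per sample; the score outputs are
  constrained only by weight decay;
* pixel-score: the same composite per pixel;
* sharpness score: L1 between `(s_wd, s_stig)` and
  `(|wd|, |stig_x| + |stig_y|)` of the image's *effective* aberration —
  for a perturbed image this includes its `∓σ_wd` offset.

Augmentations (gamma p = 0.75, mean 1, sd 0.25, applied on intensities
rescaled to [0,1]; brightness/contrast with contrast mean 1 sd 0.25,
brightness mean 0 sd 0.25; additive Gaussian noise p = 0.75, sd 0.2) run
in the raw gray domain before normalization; the noise and brightness
sigmas are interpreted on the `[−1,1]` scale (×127.5 in gray levels), the
only scale on which those values are meaningful. The contrast formula is
`I* = contrast·(I − I_mean) + I_mean + brightness` with the per-patch
mean; augmentations are applied independently to the two images of a pair,
matching physically independent acquisitions. Training is deterministic
given its seed; the returned model is the checkpoint with the best
validation loss (a deterministic replacement for "stopped after
validation-loss convergence").

`fine_tune_last_layers()` is the recalibration trainer: the convolutional
encoder is frozen (features are computed in evaluation mode, so its
parameters and normalization statistics are bit-identical afterwards) and
only the three FC layers are updated, under the faster schedule (factor
0.95 every 1000 steps, at most 50,000 steps).

## Closed-loop control and diagnostics

`correction_step()` acquires the `±σ_wd` pair at the current state, crops
`N` shared-offset patch pairs (from a fixed offset seed, so offsets repeat
across iterations and trajectories), evaluates the model on all patches in
one batch (bit-equivalent to sequential evaluation), reduces per the
configured mode and applies the result. `run_autofocus()` iterates this
and records, per iteration, the true residual state read from the
simulator by the evaluation harness — the controller itself never touches
the baseline.

Diagnostics follow the standard protocol: per-component absolute residuals
`|δ| = |ΔF_applied − ΔF_target|`; the convergence margins 1 µm (wd) and
0.25 a.u. (stigmators); OLS linearity fits of predicted vs target wd
corrections (`fit_linearity()`, via `stats::lm`); single-iteration MAE
over a dataset (`evaluate_mae()`); and an image-based cross-check that
smaller residuals correspond to higher structural similarity to the
in-focus render.

## Direction-free autofocus and recalibration

The sharpness-score model predicts magnitudes, not directions, so it is usable as an
objective for classical optimization on any instrument. The aggregated
objective over one image is `min_i s_wd,i + min_i s_stig,i` over `N`
patches (minima, because a patch can look blurry for lack of content but
never sharper than the optics allow; locations come from a fixed seed so
the objective is deterministic). `nelder_mead_autofocus()` minimizes it
with a hand-implemented downhill simplex extended by a stall rule: if the
best score has not improved within the last 5 iterations (checked at most
once per 5 iterations), the current parameters are perturbed by uniform
noise within `(±2 µm, ±0.5, ±0.5)` and the simplex restarts around the
perturbed point (simplex state handling after a stall is not otherwise
constrained; restarting is this package's documented choice, and
"no improvement" means less than 1e−12 relative decrease). The stopping
threshold is 1.05× the score of a known sharp reference state
(`compute_stop_threshold()`; on the simulator, the zero state stands in
for the one-time manual focus).

Recalibration (`generate_recalibration_dataset()`): on the modified scope,
each grid location is first auto-focused with the simplex (from a modest
unknown misfocus), then sampled aberrations (uniform within ±20 µm, ±5)
are introduced relative to the found baseline and perturbed pairs are
acquired with dwell drawn as 200 or 100 ns. Non-converged locations are
skipped with a warning. The resulting labeled samples carry the simplex's
small residual baseline error, exactly as an instrument-acquired set
would. Fine-tuning the FC head on them restores the corrector.

The modified instrument is emulated by a 90° scan rotation. Under the
beam-spot model a rotated scan negates the *apparent* stigmator vector, so
a stale model corrects wd but drives the stigmators away from zero — the
divergence signature that recalibration must repair. The working-distance
response flip is also implemented on the virtual scope but is equivalent
to a 90° kernel rotation under this forward model, so combining the two
would cancel; the scan rotation alone is used for the experiments.

## Desk-scale study conditions

All heavy experiments run at a reduced, fixed scale:

* scenes 256×256 (192×192 for small fixtures), images 128×128, patches
  64×64, `σ_wd = 5 µm`, 200 ns dwell for perturbed acquisitions;
* ground truth: 200 locations × 10 aberrations = 2000 pairs, uniform
  within ±20 µm and ±5 a.u., 80/20 sample-level shuffle split (the split
  leaks locations across sets by design, mirroring the sample-level
  protocol). Many scenes with few aberrations each are preferred over the
  reverse because small patches otherwise overfit the random anisotropy
  of individual texture realizations;
* the two-group reference plan (23 locations with ±0.5 stigmators at
  96×128 plus 17 with ±5 at 192×256, 10 aberrations each) is retained for
  the 400-sample / 320-80 split arithmetic;
* recalibration: 10 locations × 10 aberrations = 100 samples;
* convergence experiments: initial aberration (30 µm, +6, −6) — outside
  the training range, as in the reference protocol — margins 1 µm /
  0.25 a.u., N = 5 patch pairs, trajectories over fresh scenes; the
  modified-instrument evaluation draws initial aberrations uniformly from
  wd 8–12 µm, stig x −4..−2, stig y 2..4 under a fixed seed.

Desk-scale training choices (all stated here because they deviate from
the instrument-scale protocol): augmentation runs at reduced strengths
(`desk_augment_config()`: noise sd 0.05, gamma/contrast/brightness sd
0.1) because the simulator already injects physical shot and read noise
and, at 64 px patches, instrument-strength additive noise overwhelms the
blur signal; the regression head carries a fixed uniform output scale of
10 (pure conditioning — raw-unit targets span tens of µm while a fresh
linear head emits values near zero; the loss remains unweighted L1); the
patch-score variant is initialized from the trained plain encoder rather
than from scratch; iteration budgets are a few thousand AdamW steps with
best-validation checkpoint selection replacing convergence-based
stopping. The instrument benchmarks of the original study (absolute MAE
values, linearity coefficients measured on hardware, wall-clock timings)
are not reproducible on a simulator at this scale and are replaced by the
property suite in `tests/testthat/test-acceptance.R`.

### What the desk scale does and does not reach

The desk-trained controller recovers the working-distance correction
(validation MAE well under 20% of the sampling range, sign-correct
response, closed-loop contraction) and clearly demonstrates the
qualitative claims: score weighting helps on blank-region scenes, a
rotated-scan instrument breaks stigmation and recalibration repairs it.
It does **not** reach the instrument-scale convergence margins within
three iterations: near focus its stigmator accuracy plateaus around
0.5–0.8 a.u. across architectures and training budgets, an order of
magnitude above what the 0.25 a.u. margin demands. The arithmetic behind
this: with `k_s = 0.5 px/a.u.`, the margin corresponds to 0.125 px of
blur anisotropy, while the random spectral anisotropy of a single
64-px texture patch is of the same order — at the original 512-px
patches that sampling noise is ~8× smaller. The acceptance suite asserts
the printed margins anyway and records the shortfall rather than
relaxing it.

## Numerical and design choices

* Pooling floors odd sizes; valid convolutions in the stacked models,
  same-padding in the U-Net.
* Softmax weighting subtracts the maximum score before exponentiation.
* Dropout is disabled at inference (estimates are deterministic given the
  acquisition).
* The perturbed pair is acquired in the fixed order (−σ_wd, +σ_wd);
  trained models depend on this convention.
* Patch offsets are 0-based (row, col) top-left corners, uniform over all
  valid positions.
* Aberration sampling, scene synthesis, acquisition noise, training and
  simplex perturbations each draw from seeds derived deterministically
  from one root seed.
* Datasets are stored as single RDS containers (images as integer
  matrices, targets, metadata and the generating plan); model checkpoints
  as RDS plus a JSON sidecar describing architecture and normalization.
* Degenerate inputs fail loudly: kernels larger than the scene, patches
  larger than the raster, U-Net inputs not divisible by 8, empty
  prediction lists, degenerate OLS designs, fine-tuning a model without a
  three-layer FC head.

## Known limitations

* The forward model is a Gaussian blur; real SEM point-spread functions
  have structured tails, and real defocus interacts with sample topography.
* Pure-defocus information enters only through blur *magnitudes*, so a wd
  response sign flip alone is unobservable here (see above) — on real
  instruments it would not be.
* The engine is CPU-bound R/BLAS; it is sized for desk-scale models, not
  for the 512-px production architectures (which it can build and
  evaluate, but training them would be slow).
* Sharpness-score magnitudes are trained on the same simulator family; machine
  independence is demonstrated across the scan-rotation change, not across
  physically different instruments.
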