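# semfocus

Learned focus and astigmatism correction for scanning electron microscopy,
developed and tested end to end on a virtual microscope.

## The problem

High-throughput SEM acquires millions of images unattended; keeping them
sharp requires correcting three beam parameters — the working distance
`wd` (µm) and two stigmators `stig x`, `stig y` (arbitrary units) — without
an operator. Classical algorithms model the optics explicitly and tend to
need expert re-tuning per instrument and sample. semfocus implements the
data-driven alternative: a convolutional network regresses the correction

```
ΔF = (Δf_wd, Δf_stigx, Δf_stigy)
```

directly from two images acquired at a known symmetric working-distance
perturbation `±σ_wd` around the current state `F` (phase diversity — one
image cannot resolve the defocus sign, an ordered pair can). Per iteration,
N patch pairs are cropped from the two images, predicted independently, and
reduced to one correction by a mean — or by a softmax-weighted mean of
learned per-patch (or per-pixel) scores `s_i`, which suppresses
uninformative regions such as blank resin. Ideally the response is linear,
`Δf_wd = c1·Δf̃_wd + c2` with `c1 = 1`, `c2 = 0`, and the closed loop
converges within a few iterations to the margins `|δ_wd| < 1 µm`,
`|δ_stig| < 0.25`.

A second network (a direction-free sharpness score predicting `|wd|` and
`|stig x| + |stig y|` from a single image) turns Nelder–Mead simplex
optimization into a slower, machine-independent autofocus. Its role is
self-recalibration: on a modified instrument where the fast model fails,
the score-based autofocus establishes focus baselines automatically,
labeled pairs are acquired, and only the model's fully connected head is
re-trained.

Everything runs against a built-in virtual scope (anisotropic Gaussian
two-line-foci beam model, Poisson shot noise scaled by dwell time, Gaussian
read noise, band-passed texture scenes with optional blank regions), so the
whole pipeline — ground-truth generation, training, control, recalibration —
is reproducible in software. See the methods vignette
(`vignettes/semfocus-methods.Rmd`) for the model and all conventions.

## A worked example

Build the production-scale architecture and check its head against the
layer-chain arithmetic, then run a desk-scale closed loop with an oracle
to see the trajectory bookkeeping:

```r
library(semfocus)

spec <- stacked_conv_spec()
conv_stack_feature_dim(spec, 512, depth = 2)
#> [1] 6860
conv_stack_feature_dim(spec, 128, depth = 2)
#> [1] 140

scene <- scene_raster(c(192, 192), seed = 1)
scope <- virtual_scope(scene, optics_config(),
                       acquisition_config(image_shape = c(96, 96)))
oracle <- function(pair, patches) -as.numeric(scope_true_state(scope))
rec <- run_autofocus(scope, oracle,
                     control_config(n_patches = 2, patch_side = 64,
                                    max_iter = 2),
                     initial_aberration = focus_state(30, 6, -6), seed = 1)
rec$trajectory[, c("iteration", "d_wd", "d_stig_x", "d_stig_y")]
#>   iteration d_wd d_stig_x d_stig_y
#> 1         0   30        6        6
#> 2         1    0        0        0
#> 3         2    0        0        0
```

The residual columns are the per-component distances `|δ|` to the sharp
baseline after each iteration; a perfect estimator cancels the aberration
in one step, and `convergence_iteration(rec)` reports when both margins
(1 µm, 0.25 a.u.) hold. Training a real desk-scale model follows the same
surface:

```r
plan <- sampling_plan(200, 10, wd_range = 20, stig_range = 5,
                      image_shape = c(128, 128))
ds <- generate_ground_truth(plan, optics_config(), seed = 101)
split <- split_dataset(ds, fraction = 0.8, seed = 101)
fit <- train_model("plain", split, train_config(max_steps = 6000,
                                                batch_size = 8), seed = 7)
evaluate_mae(fit$model, split$validation, n_patches = 5, side = 64)$mae
```

A command-line wrapper over the same functions is installed at
`inst/cli/semfocus.R` (subcommands `simulate`, `datagen`, `train`,
`autofocus`, `deepscore-af`, `recalibrate`, `evaluate`; every run writes a
JSON manifest with seeds and file digests).

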