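test_that("augmentation honors its probability and parameter contracts", {
  patch <- matrix(runif(32^2, 40, 210), 32)
  # all probabilities zero: identity
  off <- augment_config(noise_p = 0, gamma_p = 0, bc_p = 0)
  expect_identical(augment_patch(patch, off, seed = 1), patch)
  # identity parameters with certain application: still the identity
  ident <- augment_config(noise_p = 1, noise_sd = 0, gamma_p = 1,
                          gamma_sd = 0, bc_p = 1, contrast_sd = 0,
                          brightness_sd = 0)
  expect_equal(augment_patch(patch, ident, seed = 1), patch,
               tolerance = 1e-12)
  # pure brightness: the patch mean shifts by exactly b (no clipping here)
  br <- augment_config(noise_p = 0, gamma_p = 0, bc_p = 1,
                       contrast_sd = 0, brightness_mean = 0.2,
                       brightness_sd = 0)
  shifted <- augment_patch(patch, br, seed = 1)
  expect_equal(mean(shifted) - mean(patch), 0.2 * 127.5, tolerance = 1e-9)
  # gamma fixes the endpoints 0 and 255 for any exponent
  gp <- matrix(c(0, 255, 128, 64), 2)
  gm <- augment_config(noise_p = 0, bc_p = 0, gamma_p = 1,
                       gamma_mean = 1.7, gamma_sd = 0)
  out <- augment_patch(gp, gm, seed = 2)
  expect_equal(out[1, 1], 0)
  expect_equal(out[2, 1], 255)
  expect_false(isTRUE(all.equal(out[1, 2], gp[1, 2])))
  # deterministic given seed; outputs stay in range under heavy noise
  heavy <- augment_config(noise_p = 1, noise_sd = 1)
  a1 <- augment_patch(patch, heavy, seed = 9)
  expect_identical(a1, augment_patch(patch, heavy, seed = 9))
  expect_true(all(a1 >= 0 & a1 <= 255))
})

test_that("the composite score loss mixes final and individual L1 terms", {
  tgt <- c(0, 0, 0)
  # perfect fit
  expect_equal(composite_score_loss(c(0, 0, 0), list(c(0, 0, 0)), tgt,
                                    loss_config(0.25)), 0)
  # alpha = 0 reduces to the final-prediction L1
  expect_equal(composite_score_loss(c(3, 0, 0), list(c(99, 99, 99)), tgt,
                                    loss_config(0)), 1)
  # hand-computed mixture at alpha = 0.25:
  # final L1 = 0.8, individuals L1 = (1.0, 1.4), mean 1.2
  expect_equal(composite_score_loss(c(2.4, 0, 0),
                                    list(c(3, 0, 0), c(4.2, 0, 0)), tgt,
                                    loss_config(0.25)),
               0.75 * 0.8 + 0.25 * 1.2)
  expect_error(composite_score_loss(c(1, 1, 1), list(), tgt,
                                    loss_config(0.25)), "individual")
  # nonnegative, zero iff everything matches the target
  set.seed(1)
  for (i in 1:10) {
    f <- rnorm(3); ind <- list(rnorm(3), rnorm(3)); t0 <- rnorm(3)
    l <- composite_score_loss(f, ind, t0, loss_config(0.25))
    expect_gte(l, 0)
  }
})

test_that("sharpness targets are |wd| and summed stigmator magnitudes", {
  expect_equal(unname(deepscore_target(c(0, 0, 0))), c(0, 0))
  expect_equal(unname(deepscore_target(c(5, 0, 0))), c(5, 0))
  expect_equal(unname(deepscore_target(c(-3, 1, -2))), c(3, 3))
})

test_that("the step learning-rate schedules match the stated decay laws", {
  cfg <- train_config(lr = 1e-3, decay_factor = 0.99, decay_interval = 2000)
  expect_equal(lr_at_step(0, cfg), 1e-3)
  expect_equal(lr_at_step(1999, cfg), 1e-3)
  expect_equal(lr_at_step(2000, cfg), 0.99e-3)
  expect_equal(lr_at_step(4000, cfg), 0.9801e-3)
  ft <- train_config(lr = 1e-3, decay_factor = 0.95, decay_interval = 1000)
  expect_equal(lr_at_step(1000, ft), 0.95e-3)
})

test_that("training beats the constant-zero baseline and is bit-reproducible under a fixed seed", {
  ds <- smoke_dataset()
  sp <- split_dataset(ds, seed = 2)
  no_aug <- augment_config(noise_p = 0, gamma_p = 0, bc_p = 0)
  fit1 <- train_model("plain", sp,
                      train_config(max_steps = 1500, batch_size = 8,
                                   patch_side = 48, eval_every = 300),
                      aug_cfg = no_aug, seed = 11,
                      model = build_correction_model(desk_conv_spec(), 48,
                                                     3, seed = 8))
  expect_true(all(is.finite(fit1$history$train_loss)))
  # smoke-test oracle: the trained model must clearly beat the
  # constant-zero predictor on held-out samples
  targets <- t(vapply(sp$validation$samples,
                      function(s) as.numeric(s$target), numeric(3)))
  ev <- evaluate_mae(fit1$model, sp$validation, n_patches = 3, side = 48,
                     seed = 4)
  expect_lt(ev$mae[["wd"]], 0.8 * mean(abs(targets[, 1])))
  # bit-reproducibility of the full optimization path
  cfg_s <- train_config(max_steps = 150, batch_size = 4, patch_side = 32,
                        eval_every = 50)
  fit2 <- train_model("plain", sp, cfg_s, seed = 12,
                      model = build_correction_model(smoke_spec(), 32, 3,
                                                     seed = 8))
  fit3 <- train_model("plain", sp, cfg_s, seed = 12,
                      model = build_correction_model(smoke_spec(), 32, 3,
                                                     seed = 8))
  expect_identical(fit2$history, fit3$history)
  expect_false(identical(
    fit2$history,
    train_model("plain", sp, cfg_s, seed = 13,
                model = build_correction_model(smoke_spec(), 32, 3,
                                               seed = 8))$history))
})

test_that("score-variant training steps run on all architectures", {
  ds <- tiny_dataset()
  sp <- split_dataset(ds, seed = 2)
  cfg <- train_config(max_steps = 8, batch_size = 2, patch_side = 32,
                      patches_per_sample = 3, eval_every = 4)
  fit_ps <- train_model("patch-score", sp, cfg, seed = 3,
                        model = build_correction_model(smoke_spec(), 32, 4,
                                                       seed = 8))
  expect_true(all(is.finite(fit_ps$history$train_loss)))
  fit_ds <- train_model("deepscore", sp, cfg, seed = 3,
                        model = build_deepscore_model(smoke_spec(), 32,
                                                      seed = 8))
  expect_true(all(is.finite(fit_ds$history$train_loss)))
  cfg_px <- train_config(max_steps = 3, batch_size = 1, patch_side = 32,
                         eval_every = 3)
  fit_px <- train_model("pixel-score", sp, cfg_px, seed = 3,
                        model = build_pixel_score_model(8L, seed = 8))
  expect_true(all(is.finite(fit_px$history$train_loss)))
})

test_that("fine-tuning freezes the convolutional encoder and uses the recalibration schedule", {
  ds <- tiny_dataset()
  m <- build_correction_model(smoke_spec(), 32, 3, seed = 5)
  tuned <- fine_tune_last_layers(m, ds,
                                 train_config(max_steps = 30,
                                              batch_size = 2,
                                              patch_side = 32), seed = 2)
  conv_idx <- which(vapply(m$layers, function(l) l$type == "conv_block",
                           TRUE))
  for (i in conv_idx) {
    expect_identical(tuned$layers[[i]]$params, m$layers[[i]]$params)
    expect_identical(tuned$layers[[i]]$rm, m$layers[[i]]$rm)
  }
  fc_idx <- which(vapply(m$layers, function(l) l$type == "fc", TRUE))
  expect_false(identical(tuned$layers[[fc_idx[1]]]$params$W,
                         m$layers[[fc_idx[1]]]$params$W))
  # structure guard: a model without three fully connected layers is refused
  broken <- m
  broken$layers <- m$layers[-length(m$layers)]
  expect_error(fine_tune_last_layers(broken, ds), "three fully connected")
})
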