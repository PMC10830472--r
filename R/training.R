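#' Augmentation configuration
#'
#' Each sub-augmentation fires independently with its probability and draws
#' its parameter from a Normal distribution. Augmentations run on the raw
#' 0-255 gray scale before the `[-1, 1]` rescale; the noise and brightness
#' standard deviations are expressed on the `[-1, 1]` scale (a sigma of
#' 0.2 corresponds to 25.5 gray levels) so their values keep their usual
#' meaning relative to the model input range.
#'
#' @param noise_p,noise_mean,noise_sd additive Gaussian noise.
#' @param gamma_p,gamma_mean,gamma_sd gamma adjustment (intensities
#'   internally rescaled to `[0, 1]`, `I* = I^gamma`).
#' @param bc_p,contrast_mean,contrast_sd,brightness_mean,brightness_sd
#'   brightness/contrast adjustment
#'   `I* = contrast * (I - I_mean) + I_mean + brightness` with `I_mean`
#'   the per-patch mean.
#' @return a list of class `augment_config`.
#' @export
augment_config <- function(noise_p = 0.75, noise_mean = 0, noise_sd = 0.2,
                           gamma_p = 0.75, gamma_mean = 1, gamma_sd = 0.25,
                           bc_p = 0.75, contrast_mean = 1,
                           contrast_sd = 0.25, brightness_mean = 0,
                           brightness_sd = 0.25) {
  stopifnot(noise_p >= 0, noise_p <= 1, gamma_p >= 0, gamma_p <= 1,
            bc_p >= 0, bc_p <= 1, noise_sd >= 0, gamma_sd >= 0,
            contrast_sd >= 0, brightness_sd >= 0)
  structure(as.list(environment()), class = "augment_config")
}

#' Augment a patch
#'
#' Applies (in order) gamma, brightness/contrast and additive noise, each
#' with its configured probability, then clips back to `[0, 255]`.
#' Deterministic given `seed`; with `seed = NULL` the ambient RNG stream is
#' used (as inside the training loop).
#'
#' @param patch numeric matrix, gray levels in `[0, 255]`.
#' @param cfg an [augment_config()].
#' @param seed optional integer seed.
#' @return the augmented patch.
#' @export
augment_patch <- function(patch, cfg = augment_config(), seed = NULL) {
  with_seed(seed, {
    if (cfg$gamma_p > 0 && stats::runif(1) < cfg$gamma_p) {
      g <- max(stats::rnorm(1, cfg$gamma_mean, cfg$gamma_sd), 0.05)
      patch <- 255 * (patch / 255)^g
    }
    if (cfg$bc_p > 0 && stats::runif(1) < cfg$bc_p) {
      ct <- stats::rnorm(1, cfg$contrast_mean, cfg$contrast_sd)
      br <- stats::rnorm(1, cfg$brightness_mean, cfg$brightness_sd)
      m <- mean(patch)
      patch <- ct * (patch - m) + m + br * 127.5
    }
    if (cfg$noise_p > 0 && stats::runif(1) < cfg$noise_p) {
      patch <- patch + stats::rnorm(length(patch), cfg$noise_mean * 127.5,
                                    cfg$noise_sd * 127.5)
    }
    pmin(pmax(patch, 0), 255)
  })
}

#' Desk-scale augmentation settings
#'
#' The [augment_config()] defaults model instrument-level variability
#' (detector gain drift, contrast changes) at full strength. On the
#' virtual scope that variability is absent and the acquisition itself
#' already injects shot and read noise, so the desk-scale training
#' protocol uses reduced augmentation strengths; at 64 px patches the
#' full-strength additive noise would dominate the blur signal outright.
#'
#' @return an [augment_config()] with desk-scale strengths.
#' @export
desk_augment_config <- function() {
  augment_config(noise_sd = 0.05, gamma_sd = 0.1, contrast_sd = 0.1,
                 brightness_sd = 0.1)
}

#' Loss mixing configuration for the score models
#'
#' @param alpha mixing weight between the loss of the (score-weighted)
#'   final prediction and the mean loss of the individual predictions.
#' @return a list of class `loss_config`.
#' @export
loss_config <- function(alpha = 0.25) {
  stopifnot(alpha >= 0, alpha <= 1)
  structure(list(alpha = alpha), class = "loss_config")
}

l1_loss <- function(a, b) mean(abs(as.numeric(a) - as.numeric(b)))

#' Composite loss of a score-weighted prediction
#'
#' `(1 - alpha) * L1(final, target) + alpha * mean_i L1(individual_i,
#' target)` where L1 is the unweighted mean absolute error over the three
#' correction components.
#'
#' @param final the reduced (weighted) correction estimate.
#' @param individuals list of the individual correction estimates.
#' @param target the target correction.
#' @param cfg a [loss_config()].
#' @return scalar loss.
#' @export
composite_score_loss <- function(final, individuals, target,
                                 cfg = loss_config()) {
  if (cfg$alpha > 0 && length(individuals) == 0L)
    stop("individual predictions required when alpha > 0", call. = FALSE)
  li <- if (length(individuals)) {
    mean(vapply(individuals, l1_loss, 0, b = target))
  } else 0
  (1 - cfg$alpha) * l1_loss(final, target) + cfg$alpha * li
}

#' Sharpness-score training target for an aberration
#'
#' The working-distance score targets `|wd|`; the stigmation score targets
#' the summed stigmator magnitudes `|stig_x| + |stig_y|`.
#'
#' @param aberration an aberration triple.
#' @return `c(s_wd, s_stig)`.
#' @export
deepscore_target <- function(aberration) {
  a <- as.numeric(aberration)
  c(s_wd = abs(a[1]), s_stig = abs(a[2]) + abs(a[3]))
}

#' Training configuration
#'
#' @param lr base learning rate (AdamW).
#' @param decay_factor,decay_interval step scheduler: the rate is
#'   multiplied by `decay_factor` every `decay_interval` steps.
#' @param batch_size samples per step.
#' @param patches_per_sample patch pairs per sample for the patch-score
#'   variant (default 5).
#' @param patch_side patch side, pixels.
#' @param max_steps iteration budget.
#' @param weight_decay AdamW decoupled weight decay.
#' @param eval_every validation-loss interval, steps.
#' @return a list of class `train_config`.
#' @export
train_config <- function(lr = 1e-3, decay_factor = 0.99,
                         decay_interval = 2000, batch_size = 16,
                         patches_per_sample = 5, patch_side = 64,
                         max_steps = 5000, weight_decay = 0.01,
                         eval_every = 250) {
  stopifnot(decay_factor > 0, decay_factor <= 1, max_steps > 0)
  structure(as.list(environment()), class = "train_config")
}

#' Learning rate at a training step
#'
#' `lr0 * factor^floor(step / interval)`.
#'
#' @param step 0-based step index.
#' @param cfg a [train_config()].
#' @return the learning rate.
#' @export
lr_at_step <- function(step, cfg) {
  stopifnot(step >= 0)
  cfg$lr * cfg$decay_factor^(step %/% cfg$decay_interval)
}

sample_target_matrix <- function(samples) {
  t(vapply(samples, function(s) as.numeric(s$target), numeric(3)))
}

# Deterministic validation patches: one centered patch pair per validation
# sample (capped), without augmentation.
make_val_patches <- function(samples, side, cap = 48L) {
  n <- min(length(samples), cap)
  lapply(seq_len(n), function(i) {
    p <- samples[[i]]$pair
    r0 <- (nrow(p$minus) - side) %/% 2L
    c0 <- (ncol(p$minus) - side) %/% 2L
    list(minus = p$minus[r0 + seq_len(side), c0 + seq_len(side)],
         plus = p$plus[r0 + seq_len(side), c0 + seq_len(side)])
  })
}

#' Train a model variant
#'
#' Per step: draw a batch of training samples, crop shared-offset patch
#' pairs, augment the two images of each pair independently, rescale to
#' `[-1, 1]`, take an AdamW step on the variant's loss under the step
#' learning-rate schedule. Variants: `"plain"` (L1 on the 3-component
#' output), `"patch-score"` (composite loss on the softmax-weighted average
#' of `patches_per_sample` predictions), `"pixel-score"` (per-pixel
#' composite loss on the U-Net output), `"deepscore"` (L1 on the two
#' magnitude scores of a single image; the image's effective defocus
#' includes its +/-sigma_wd perturbation). The returned model is the
#' checkpoint with the best recorded validation loss. Deterministic given
#' `seed`; a non-finite loss aborts with a diagnostic.
#'
#' @param variant one of `"plain"`, `"patch-score"`, `"pixel-score"`,
#'   `"deepscore"`.
#' @param split a [split_dataset()] result (or a `sem_dataset`, trained
#'   without validation tracking).
#' @param train_cfg a [train_config()].
#' @param aug_cfg an [augment_config()].
#' @param loss_cfg a [loss_config()] (score variants).
#' @param seed integer seed.
#' @param model optionally a pre-built model to continue training.
#' @return list with `model` and `history` (data frame of step, lr,
#'   training loss, validation loss).
#' @export
train_model <- function(variant = c("plain", "patch-score", "pixel-score",
                                    "deepscore"),
                        split, train_cfg = train_config(),
                        aug_cfg = augment_config(),
                        loss_cfg = loss_config(), seed = 1, model = NULL) {
  variant <- match.arg(variant)
  if (inherits(split, "sem_dataset"))
    split <- list(train = split, validation = subset_dataset(split, integer(0)))
  train <- split$train$samples
  val <- split$validation$samples
  if (!length(train)) stop("empty training set", call. = FALSE)
  side <- train_cfg$patch_side
  if (is.null(model)) {
    small <- side < 128L
    model <- switch(variant,
      plain = build_correction_model(
        if (small) desk_conv_spec() else stacked_conv_spec(), side, 3,
        seed = derive_seed(seed, 99L)),
      `patch-score` = build_correction_model(
        if (small) desk_conv_spec() else stacked_conv_spec(), side, 4,
        seed = derive_seed(seed, 99L)),
      `pixel-score` = build_pixel_score_model(seed = derive_seed(seed, 99L)),
      deepscore = build_deepscore_model(
        if (small) desk_score_spec() else deepscore_conv_spec(), side,
        seed = derive_seed(seed, 99L)))
  }
  is_unet <- inherits(model, "sem_unet")
  targets <- sample_target_matrix(train)
  val_patches <- if (length(val)) make_val_patches(val, side)
  val_targets <- if (length(val))
    sample_target_matrix(val)[seq_along(val_patches), , drop = FALSE]

  opt <- if (is_unet) unet_adamw_init(model) else adamw_init(model)
  history <- vector("list", train_cfg$max_steps %/% train_cfg$eval_every + 1L)
  hrow <- 0L
  best <- list(val = Inf, model = model)

  eval_val_loss <- function(model) {
    if (!length(val)) return(NA_real_)
    if (variant == "deepscore") {
      imgs <- lapply(val_patches, `[[`, "minus")
      out <- predict_sharpness(model, imgs)
      tg <- t(vapply(seq_along(imgs), function(i) {
        ab <- -val_targets[i, ]
        deepscore_target(c(ab[1] - val[[i]]$pair$sigma_wd, ab[2], ab[3]))
      }, numeric(2)))
      return(mean(abs(out - tg)))
    }
    if (is_unet) {
      est <- predict_dense(model, val_patches)$estimates
    } else {
      est <- predict_corrections(model, val_patches)$estimates
    }
    mean(abs(est - val_targets))
  }

  with_seed(seed, {
    for (step in seq_len(train_cfg$max_steps)) {
      lr <- lr_at_step(step - 1L, train_cfg)
      idx <- sample.int(length(train), train_cfg$batch_size, replace = TRUE)
      if (variant == "deepscore") {
        imgs <- vector("list", length(idx))
        tg <- matrix(0, length(idx), 2)
        for (k in seq_along(idx)) {
          s <- train[[idx[k]]]
          which_img <- sample(c(-1, 1), 1)
          p <- crop_patch_pairs(s$pair, 1L, side, seed = NULL)[[1]]
          img <- if (which_img < 0) p$minus else p$plus
          imgs[[k]] <- augment_patch(img, aug_cfg)
          ab <- -targets[idx[k], ]
          tg[k, ] <- deepscore_target(c(ab[1] + which_img * s$pair$sigma_wd,
                                        ab[2], ab[3]))
        }
        x <- patches_to_tensor(imgs, 1L)
        fw <- model_forward(model, x, training = TRUE)
        model <- fw$model
        diffm <- fw$out - tg
        loss <- mean(abs(diffm))
        gout <- sign(diffm) / length(diffm)
      } else if (variant == "patch-score") {
        npp <- train_cfg$patches_per_sample
        patches <- list()
        for (k in seq_along(idx)) {
          pp <- crop_patch_pairs(train[[idx[k]]]$pair, npp, side, seed = NULL)
          pp <- lapply(pp, function(p) list(
            minus = augment_patch(p$minus, aug_cfg),
            plus = augment_patch(p$plus, aug_cfg)))
          patches <- c(patches, pp)
        }
        x <- patches_to_tensor(patches, 2L)
        fw <- model_forward(model, x, training = TRUE)
        model <- fw$model
        out <- fw$out
        B <- length(idx)
        gout <- matrix(0, nrow(out), 4L)
        loss <- 0
        alpha <- loss_cfg$alpha
        for (k in seq_len(B)) {
          rows <- (k - 1L) * npp + seq_len(npp)
          e <- out[rows, 1:3, drop = FALSE]
          s <- out[rows, 4L]
          w <- exp(s - max(s)); w <- w / sum(w)
          fin <- colSums(e * w)
          tk <- targets[idx[k], ]
          sf <- sign(fin - tk)
          si <- sign(sweep(e, 2, tk))
          loss <- loss + (1 - alpha) * mean(abs(fin - tk)) +
            alpha * mean(abs(sweep(e, 2, tk)))
          ge <- (1 - alpha) / 3 * outer(w, sf) + alpha / (3 * npp) * si
          gs <- (1 - alpha) / 3 *
            w * as.numeric((e - rep(fin, each = npp)) %*% sf)
          gout[rows, 1:3] <- ge
          gout[rows, 4L] <- gs
        }
        loss <- loss / B
        gout <- gout / B
      } else if (variant == "pixel-score") {
        patches <- lapply(idx, function(i) {
          p <- crop_patch_pairs(train[[i]]$pair, 1L, side, seed = NULL)[[1]]
          list(minus = augment_patch(p$minus, aug_cfg),
               plus = augment_patch(p$plus, aug_cfg))
        })
        x <- patches_to_tensor(patches, 2L)
        fw <- unet_forward(model, x, training = TRUE)
        out <- fw$out
        d <- dim(out)
        P <- d[1] * d[2]
        B <- length(idx)
        alpha <- loss_cfg$alpha
        gout <- array(0, d)
        loss <- 0
        for (k in seq_len(B)) {
          m <- out[, , , k]
          tk <- targets[idx[k], ]
          s <- as.vector(m[, , 4L])
          w <- exp(s - max(s)); w <- w / sum(w)
          cfield <- matrix(m[, , 1:3], P, 3L)
          fin <- colSums(cfield * w)
          sf <- sign(fin - tk)
          dev <- sweep(cfield, 2, tk)
          loss <- loss + (1 - alpha) * mean(abs(fin - tk)) +
            alpha * mean(abs(dev))
          gc <- (1 - alpha) / 3 * outer(w, sf) +
            alpha / (3 * P) * sign(dev)
          gs <- (1 - alpha) / 3 *
            w * as.numeric((cfield - rep(fin, each = P)) %*% sf)
          gout[, , 1:3, k] <- array(gc, c(d[1], d[2], 3L))
          gout[, , 4L, k] <- gs
        }
        loss <- loss / B
        gout <- gout / B
      } else {
        patches <- lapply(idx, function(i) {
          p <- crop_patch_pairs(train[[i]]$pair, 1L, side, seed = NULL)[[1]]
          list(minus = augment_patch(p$minus, aug_cfg),
               plus = augment_patch(p$plus, aug_cfg))
        })
        x <- patches_to_tensor(patches, 2L)
        fw <- model_forward(model, x, training = TRUE)
        model <- fw$model
        diffm <- fw$out - targets[idx, , drop = FALSE]
        loss <- mean(abs(diffm))
        gout <- sign(diffm) / length(diffm)
      }
      if (!is.finite(loss))
        stop(sprintf("training diverged (non-finite loss at step %d)", step),
             call. = FALSE)
      if (is_unet) {
        grads <- unet_backward(model, fw$caches, gout)
        up <- unet_adamw_step(model, grads, opt, lr, step,
                              train_cfg$weight_decay)
      } else {
        grads <- model_backward(model, fw$caches, gout)
        up <- adamw_step(model, grads, opt, lr, step, train_cfg$weight_decay)
      }
      model <- up$model
      opt <- up$state
      if (step %% train_cfg$eval_every == 0L || step == train_cfg$max_steps) {
        vl <- eval_val_loss(model)
        hrow <- hrow + 1L
        history[[hrow]] <- data.frame(step = step, lr = lr,
                                      train_loss = loss, val_loss = vl)
        if (is.finite(vl) && vl < best$val) best <- list(val = vl,
                                                         model = model)
      }
    }
  })
  history <- do.call(rbind, history[seq_len(hrow)])
  final <- if (is.finite(best$val)) best$model else model
  list(model = final, history = history)
}

#' Fine-tune only the fully connected head
#'
#' Recalibration training: the convolutional encoder is frozen (its
#' parameters and normalization statistics are untouched; features are
#' computed in evaluation mode) and only the three fully connected layers
#' receive AdamW updates, under the faster-decaying recalibration schedule
#' (factor 0.95 every 1000 steps, at most 50,000 steps).
#'
#' @param model a trained stacked correction `sem_model`.
#' @param dataset a `sem_dataset` or [split_dataset()] result.
#' @param train_cfg a [train_config()]; its `decay_factor`,
#'   `decay_interval` are overridden to 0.95 / 1000 and `max_steps` capped
#'   at 50,000.
#' @param aug_cfg an [augment_config()].
#' @param seed integer seed.
#' @return the fine-tuned model.
#' @export
fine_tune_last_layers <- function(model, dataset,
                                  train_cfg = train_config(),
                                  aug_cfg = augment_config(), seed = 1) {
  if (!inherits(model, "sem_model") || inherits(model, "sem_unet"))
    stop("fine-tuning requires a stacked convolutional model", call. = FALSE)
  fc_idx <- which(vapply(model$layers, function(l) l$type == "fc", TRUE))
  if (length(fc_idx) != 3L)
    stop("model must end in three fully connected layers", call. = FALSE)
  samples <- if (inherits(dataset, "sem_dataset")) dataset$samples
             else dataset$train$samples
  if (!length(samples)) stop("empty fine-tuning set", call. = FALSE)
  cfg <- train_cfg
  cfg$decay_factor <- 0.95
  cfg$decay_interval <- 1000
  cfg$max_steps <- min(cfg$max_steps, 50000L)
  side <- cfg$patch_side
  targets <- sample_target_matrix(samples)
  n_body <- fc_idx[1] - 1L
  head <- model
  head$layers <- model$layers[fc_idx]
  opt <- adamw_init(head)
  with_seed(seed, {
    for (step in seq_len(cfg$max_steps)) {
      lr <- lr_at_step(step - 1L, cfg)
      idx <- sample.int(length(samples), cfg$batch_size, replace = TRUE)
      patches <- lapply(idx, function(i) {
        p <- crop_patch_pairs(samples[[i]]$pair, 1L, side, seed = NULL)[[1]]
        list(minus = augment_patch(p$minus, aug_cfg),
             plus = augment_patch(p$plus, aug_cfg))
      })
      x <- patches_to_tensor(patches, model$depth)
      for (i in seq_len(n_body))
        x <- layer_forward(model$layers[[i]], x, training = FALSE)$y
      fw <- model_forward(head, x, training = FALSE)
      diffm <- fw$out[, 1:3, drop = FALSE] -
        targets[idx, , drop = FALSE]
      loss <- mean(abs(diffm))
      if (!is.finite(loss))
        stop("fine-tuning diverged (non-finite loss)", call. = FALSE)
      gout <- matrix(0, nrow(fw$out), ncol(fw$out))
      gout[, 1:3] <- sign(diffm) / length(diffm)
      grads <- model_backward(head, fw$caches, gout)
      up <- adamw_step(head, grads, opt, lr, step, cfg$weight_decay)
      head <- up$model
      opt <- up$state
    }
  })
  model$layers[fc_idx] <- head$layers
  model
}
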