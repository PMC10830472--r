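#' Controller configuration
#'
#' @param n_patches number of patch pairs per iteration (independent
#'   predictions reduced to one correction).
#' @param patch_side patch side, pixels.
#' @param max_iter maximum closed-loop iterations.
#' @param reduction `"mean"` (plain average), `"patch-score"`
#'   (softmax-weighted by the model's score output) or `"pixel-score"`
#'   (dense predictions reduced per patch, then averaged).
#' @param dwell_time optional dwell override for the perturbed
#'   acquisitions, ns.
#' @param offset_seed seed of the fixed patch-offset sequence; the same
#'   offsets are reused across iterations (and across trajectories sharing
#'   a configuration), keeping trajectory comparisons paired.
#' @param wd_margin,stig_margin convergence margins: focus is restored when
#'   every residual is below its margin (1 um / 0.25 a.u.).
#' @return a list of class `control_config`.
#' @export
control_config <- function(n_patches = 5, patch_side = 64, max_iter = 10,
                           reduction = c("mean", "patch-score",
                                         "pixel-score"),
                           dwell_time = NULL, offset_seed = 1,
                           wd_margin = 1, stig_margin = 0.25) {
  stopifnot(n_patches >= 1, max_iter >= 1)
  reduction <- match.arg(reduction)
  structure(list(n_patches = as.integer(n_patches),
                 patch_side = as.integer(patch_side),
                 max_iter = as.integer(max_iter), reduction = reduction,
                 dwell_time = dwell_time, offset_seed = offset_seed,
                 wd_margin = wd_margin, stig_margin = stig_margin),
            class = "control_config")
}

reduce_predictions <- function(model, patches, reduction) {
  if (is.function(model)) stop("internal: oracle handled by caller")
  if (reduction == "pixel-score") {
    est <- predict_dense(model, patches)$estimates
    return(reduce_plain_mean(est))
  }
  pr <- predict_corrections(model, patches)
  if (reduction == "patch-score") {
    if (is.null(pr$scores))
      stop("patch-score reduction needs a 4-output model", call. = FALSE)
    weighted_correction(pr$estimates, pr$scores)
  } else {
    reduce_plain_mean(pr$estimates)
  }
}

#' One closed-loop correction iteration
#'
#' Acquires the perturbed pair at the scope's current state, crops
#' `n_patches` shared-offset patch pairs, runs the model on all of them in
#' one batch, reduces the predictions per the configured mode, applies the
#' reduced correction to the scope and returns it. `model` may also be a
#' function `(pair, patches) -> correction` (used for oracle controllers
#' in closed-loop analyses).
#'
#' @param scope a [virtual_scope()].
#' @param model a correction model, pixel-score model, or oracle function.
#' @param cfg a [control_config()].
#' @param seed acquisition-noise seed for this iteration.
#' @return the applied correction as a [focus_state()].
#' @export
correction_step <- function(scope, model, cfg = control_config(), seed = 1) {
  pair <- scope_acquire_pair(scope, seed = seed,
                             dwell_time = cfg$dwell_time)
  patches <- crop_patch_pairs(pair, cfg$n_patches, cfg$patch_side,
                              shared_offset = TRUE, seed = cfg$offset_seed)
  delta <- if (is.function(model)) {
    as_focus_state(model(pair, patches))
  } else {
    reduce_predictions(model, patches, cfg$reduction)
  }
  scope_apply_correction(scope, delta)
  delta
}

#' Per-component absolute residual of a correction
#'
#' `|applied - target|` componentwise; the target correction is the
#' negated introduced aberration.
#'
#' @param applied applied correction triple.
#' @param target target correction triple.
#' @return named numeric vector `c(wd, stig_x, stig_y)`.
#' @export
residual <- function(applied, target) {
  r <- abs(as.numeric(applied)[1:3] - as.numeric(target)[1:3])
  names(r) <- c("wd", "stig_x", "stig_y")
  r
}

#' Run a closed-loop autofocus trajectory
#'
#' Introduces `initial_aberration` on the scope, then iterates
#' [correction_step()] up to `cfg$max_iter` times, recording the residual
#' focus-state deviation from the sharp baseline after every iteration.
#' The residuals are read from the simulator's true state by this harness;
#' the controller itself never sees them.
#'
#' @param scope a [virtual_scope()].
#' @param model model or oracle function (see [correction_step()]).
#' @param cfg a [control_config()].
#' @param initial_aberration the introduced aberration triple.
#' @param seed root seed for the per-iteration acquisition noise.
#' @return an object of class `trajectory_record`: data frame `trajectory`
#'   with per-iteration state, applied correction and absolute residuals,
#'   plus the initial aberration and configuration.
#' @export
run_autofocus <- function(scope, model, cfg = control_config(),
                          initial_aberration = focus_state(30, 6, -6),
                          seed = 1) {
  initial_aberration <- as_focus_state(initial_aberration)
  scope_set_state(scope, initial_aberration)
  rows <- vector("list", cfg$max_iter + 1L)
  st <- scope_true_state(scope)
  rows[[1]] <- data.frame(iteration = 0L, wd = st[[1]], stig_x = st[[2]],
                          stig_y = st[[3]], est_wd = NA_real_,
                          est_stig_x = NA_real_, est_stig_y = NA_real_,
                          d_wd = abs(st[[1]]), d_stig_x = abs(st[[2]]),
                          d_stig_y = abs(st[[3]]))
  for (it in seq_len(cfg$max_iter)) {
    delta <- correction_step(scope, model, cfg, seed = derive_seed(seed, it))
    st <- scope_true_state(scope)
    rows[[it + 1L]] <- data.frame(iteration = it, wd = st[[1]],
                                  stig_x = st[[2]], stig_y = st[[3]],
                                  est_wd = delta[[1]], est_stig_x = delta[[2]],
                                  est_stig_y = delta[[3]],
                                  d_wd = abs(st[[1]]),
                                  d_stig_x = abs(st[[2]]),
                                  d_stig_y = abs(st[[3]]))
  }
  structure(list(trajectory = do.call(rbind, rows),
                 initial_aberration = initial_aberration, config = cfg),
            class = "trajectory_record")
}

#' First iteration at which both convergence margins hold
#'
#' @param record a `trajectory_record`.
#' @param wd_margin,stig_margin margins, um and a.u.
#' @return the earliest iteration with `|d_wd| < wd_margin` and both
#'   stigmator residuals `< stig_margin`, or `Inf` if never reached.
#' @export
convergence_iteration <- function(record, wd_margin = 1,
                                  stig_margin = 0.25) {
  tr <- record$trajectory
  ok <- tr$d_wd < wd_margin & tr$d_stig_x < stig_margin &
    tr$d_stig_y < stig_margin
  if (any(ok)) min(tr$iteration[ok]) else Inf
}

#' Ordinary-least-squares linearity fit of predicted vs target corrections
#'
#' Fits `predicted = c1 * target + c2`. An ideal correction model has
#' `c1 = 1`, `c2 = 0`.
#'
#' @param target target working-distance corrections.
#' @param predicted model-predicted corrections.
#' @return a list of class `ols_fit` with `c1`, `c2`, `se_c1`, `se_c2`.
#' @export
fit_linearity <- function(target, predicted) {
  stopifnot(length(target) == length(predicted))
  if (length(target) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::var(target) == 0)
    stop("degenerate design: all targets equal", call. = FALSE)
  fit <- stats::lm(predicted ~ target)
  # noiseless inputs give an exactly perfect fit; the SEs are then zero
  sm <- suppressWarnings(summary(fit))$coefficients
  structure(list(c1 = unname(coef(fit)[2]), c2 = unname(coef(fit)[1]),
                 se_c1 = sm[2, 2], se_c2 = sm[1, 2]),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("<ols_fit> c1 = %.4f +/- %.4f, c2 = %.4f +/- %.4f\n",
              x$c1, x$se_c1, x$c2, x$se_c2))
  invisible(x)
}

#' Single-iteration mean absolute error of a model on a dataset
#'
#' For every sample, predicts once from `n_patches` patch pairs cropped
#' from the stored perturbed pair and compares the reduced estimate with
#' the target correction.
#'
#' @param model correction model (3- or 4-output), pixel-score model, or
#'   oracle function of the target.
#' @param dataset a `sem_dataset`.
#' @param n_patches patch pairs per sample.
#' @param side patch side, pixels.
#' @param seed offsets seed.
#' @param reduction reduction mode, as in [control_config()].
#' @return list with `mae` and `sd` (named per component) and the
#'   per-sample absolute error matrix `errors`.
#' @export
evaluate_mae <- function(model, dataset, n_patches = 5, side = 64, seed = 1,
                         reduction = "mean") {
  samples <- dataset$samples
  stopifnot(length(samples) > 0)
  errs <- matrix(0, length(samples), 3L,
                 dimnames = list(NULL, c("wd", "stig_x", "stig_y")))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    patches <- crop_patch_pairs(s$pair, n_patches, side,
                                seed = derive_seed(seed, i))
    est <- if (is.function(model)) {
      as_focus_state(model(s$pair, patches))
    } else {
      reduce_predictions(model, patches, reduction)
    }
    errs[i, ] <- residual(est, s$target)
  }
  list(mae = colMeans(errs), sd = apply(errs, 2, stats::sd), errors = errs)
}

#' Export a trajectory record to CSV
#'
#' @param record a `trajectory_record`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(record, path) {
  utils::write.csv(record$trajectory, path, row.names = FALSE)
  invisible(path)
}
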