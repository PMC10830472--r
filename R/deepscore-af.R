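#' Simplex autofocus configuration
#'
#' @param init_step initial simplex step per parameter `(um, a.u., a.u.)`.
#' @param stall_window iterations without improvement before the stall
#'   perturbation fires (checked at most once per window).
#' @param perturb_ranges uniform perturbation half-ranges
#'   `(+/-2 um, +/-0.5, +/-0.5)`.
#' @param threshold stopping threshold on the aggregated score (see
#'   [compute_stop_threshold()]).
#' @param max_eval maximum score evaluations.
#' @param seed seed for the stall perturbation draws.
#' @return a list of class `simplex_config`.
#' @export
simplex_config <- function(init_step = c(2, 0.5, 0.5), stall_window = 5,
                           perturb_ranges = c(2, 0.5, 0.5),
                           threshold = NULL, max_eval = 200, seed = 1) {
  stopifnot(stall_window >= 1, is.null(threshold) || threshold > 0)
  structure(list(init_step = init_step,
                 stall_window = as.integer(stall_window),
                 perturb_ranges = perturb_ranges, threshold = threshold,
                 max_eval = as.integer(max_eval), seed = seed),
            class = "simplex_config")
}

#' Aggregate per-patch sharpness scores into a single objective
#'
#' The minimum over patches is taken independently for each score type and
#' the two minima are summed: `min_i s_wd,i + min_i s_stig,i`. Taking
#' minima makes the aggregate robust to patches that look blurry for lack
#' of content rather than lack of focus.
#'
#' @param patch_scores n x 2 matrix (columns `s_wd`, `s_stig`) or list of
#'   2-vectors.
#' @return scalar aggregated score.
#' @export
aggregate_sharpness_score <- function(patch_scores) {
  if (is.list(patch_scores) && !is.matrix(patch_scores))
    patch_scores <- do.call(rbind, lapply(patch_scores, as.numeric))
  if (is.null(dim(patch_scores)))
    patch_scores <- matrix(patch_scores, nrow = 1)
  if (nrow(patch_scores) == 0L)
    stop("no patch scores to aggregate", call. = FALSE)
  min(patch_scores[, 1]) + min(patch_scores[, 2])
}

#' Evaluate the aggregated sharpness score at a focus state
#'
#' Sets the scope to `state`, acquires one image, crops `n_patches`
#' single-image patches (locations drawn from the fixed `seed`, so they are
#' identical across calls), scores each independently and aggregates. The
#' whole evaluation is a deterministic function of `(state, seed)`.
#'
#' @param scope a [virtual_scope()].
#' @param score_model a deepscore `sem_model`.
#' @param state the [focus_state()] to evaluate.
#' @param n_patches patches per image (default 10).
#' @param side patch side, pixels.
#' @param seed fixed seed for patch locations and acquisition noise.
#' @param dwell_time optional dwell override, ns.
#' @return scalar score (lower is sharper).
#' @export
score_at_state <- function(scope, score_model, state, n_patches = 10,
                           side = 64, seed = 1, dwell_time = NULL) {
  scope_set_state(scope, state)
  if (is.function(score_model)) return(score_model(state))
  img <- scope_acquire_image(scope, seed = derive_seed(seed, 1L),
                             dwell_time = dwell_time)
  crops <- crop_patch_pairs(list(minus = img, plus = img), n_patches, side,
                            seed = derive_seed(seed, 2L))
  imgs <- lapply(crops, `[[`, "minus")
  aggregate_sharpness_score(predict_sharpness(score_model, imgs))
}

new_simplex <- function(x0, step) {
  sim <- matrix(rep(x0, 4L), 4L, 3L, byrow = TRUE)
  for (i in 1:3) sim[i + 1L, i] <- sim[i + 1L, i] + step[i]
  sim
}

#' Machine-independent simplex autofocus on a sharpness score
#'
#' Minimizes the aggregated sharpness score over (wd, stig_x, stig_y) with
#' the Nelder-Mead downhill simplex, extended with a stall perturbation:
#' whenever the best score has not improved over the last `stall_window`
#' iterations (checked at most once per window), the current best
#' parameters are perturbed with uniform noise within `perturb_ranges` and
#' the simplex is re-initialized around the perturbed point. Terminates
#' when the score drops to `threshold` or the evaluation budget is spent;
#' the scope is left at the best state found.
#'
#' @param scope a [virtual_scope()].
#' @param score_model a deepscore `sem_model`.
#' @param cfg a [simplex_config()]; its `threshold` must be set (use
#'   [compute_stop_threshold()]).
#' @param n_patches,side,score_seed passed to [score_at_state()].
#' @return list with `state` (best [focus_state()]), `score`, `converged`,
#'   `n_eval`, `log` (data frame of evaluations) and `n_perturb`.
#' @export
nelder_mead_autofocus <- function(scope, score_model,
                                  cfg = simplex_config(), n_patches = 10,
                                  side = 64, score_seed = 1) {
  if (is.null(cfg$threshold))
    stop("simplex_config$threshold must be set", call. = FALSE)
  n_eval <- 0L
  log_rows <- list()
  fev <- function(x) {
    n_eval <<- n_eval + 1L
    s <- score_at_state(scope, score_model, focus_state(x[1], x[2], x[3]),
                        n_patches, side, seed = score_seed)
    log_rows[[n_eval]] <<- data.frame(eval = n_eval, wd = x[1],
                                      stig_x = x[2], stig_y = x[3],
                                      score = s)
    s
  }
  finish <- function(x, fx, converged) {
    scope_set_state(scope, focus_state(x[1], x[2], x[3]))
    list(state = focus_state(x[1], x[2], x[3]), score = fx,
         converged = converged, n_eval = n_eval, n_iter = it,
         log = do.call(rbind, log_rows), n_perturb = n_perturb,
         perturbs = do.call(rbind, perturb_rows))
  }
  n_perturb <- 0L
  perturb_rows <- list()
  it <- 0L
  x0 <- as.numeric(scope_true_state(scope))
  f0 <- fev(x0)
  if (f0 <= cfg$threshold) return(finish(x0, f0, TRUE))
  sim <- new_simplex(x0, cfg$init_step)
  fx <- c(f0, apply(sim[2:4, , drop = FALSE], 1, fev))
  best_hist <- min(fx)
  iters_since_check <- 0L
  with_seed(cfg$seed, {
    repeat {
      it <- it + 1L
      iters_since_check <- iters_since_check + 1L
      ord <- order(fx)
      sim <- sim[ord, , drop = FALSE]
      fx <- fx[ord]
      if (fx[1] <= cfg$threshold) return(finish(sim[1, ], fx[1], TRUE))
      if (n_eval >= cfg$max_eval) return(finish(sim[1, ], fx[1], FALSE))
      # stall-perturbation extension
      best_hist <- c(best_hist, fx[1])
      if (iters_since_check >= cfg$stall_window &&
          length(best_hist) > cfg$stall_window) {
        prev <- best_hist[length(best_hist) - cfg$stall_window]
        if (fx[1] >= prev - 1e-12 * max(abs(prev), 1)) {
          n_perturb <- n_perturb + 1L
          noise <- stats::runif(3, -cfg$perturb_ranges, cfg$perturb_ranges)
          xp <- sim[1, ] + noise
          perturb_rows[[n_perturb]] <- data.frame(iter = it,
                                                  d_wd = noise[1],
                                                  d_stig_x = noise[2],
                                                  d_stig_y = noise[3])
          sim <- new_simplex(xp, cfg$init_step)
          fx <- apply(sim, 1, fev)
          iters_since_check <- 0L
          next
        }
        iters_since_check <- 0L
      }
      xo <- colMeans(sim[1:3, , drop = FALSE])
      xr <- xo + (xo - sim[4, ])
      fr <- fev(xr)
      if (fr < fx[1]) {
        xe <- xo + 2 * (xo - sim[4, ])
        fe <- fev(xe)
        if (fe < fr) { sim[4, ] <- xe; fx[4] <- fe }
        else { sim[4, ] <- xr; fx[4] <- fr }
      } else if (fr < fx[3]) {
        sim[4, ] <- xr; fx[4] <- fr
      } else {
        xc <- xo + 0.5 * (sim[4, ] - xo)
        fc <- fev(xc)
        if (fc < fx[4]) { sim[4, ] <- xc; fx[4] <- fc }
        else {
          for (i in 2:4) {
            sim[i, ] <- sim[1, ] + 0.5 * (sim[i, ] - sim[1, ])
            fx[i] <- fev(sim[i, ])
          }
        }
      }
    }
  })
}

#' Derive the simplex stopping threshold from a known sharp state
#'
#' Evaluates the aggregated score at a reference sharp state (on the
#' simulator: zero aberration, the stand-in for a one-time manual focus)
#' and multiplies it by 1.05.
#'
#' @inheritParams score_at_state
#' @param reference_state the sharp reference (default zero aberration).
#' @return scalar threshold.
#' @export
compute_stop_threshold <- function(scope, score_model,
                                   reference_state = focus_state(0, 0, 0),
                                   n_patches = 10, side = 64, seed = 1) {
  1.05 * score_at_state(scope, score_model, reference_state, n_patches,
                        side, seed = seed)
}

#' Auto-generate a recalibration dataset on a (modified) scope
#'
#' At each grid location of the plan a fresh scene is rendered and the
#' scope arrives with an unknown modest misfocus; the score-based simplex
#' autofocus establishes the focus baseline, then each sampled aberration
#' is introduced relative to that baseline and a perturbed pair is
#' acquired (dwell drawn from the plan's options per sample). Locations
#' where the autofocus does not converge are skipped with a warning. The
#' stopping threshold is derived once from the first location's sharp
#' state, standing in for the one-time manual focus.
#'
#' @param score_model a deepscore `sem_model` trained on the original
#'   setup.
#' @param plan a [sampling_plan()] (e.g. [recalibration_plan()]).
#' @param optics an [optics_config()] of the new setup.
#' @param seed root seed.
#' @param wd_response,rotate_scan modified-instrument options of
#'   [virtual_scope()].
#' @param simplex_cfg a [simplex_config()] (threshold may be `NULL`; it is
#'   then computed here).
#' @param n_patches,side score-evaluation settings.
#' @param initial_misfocus half-ranges of the uniform initial misfocus at
#'   each location, `(um, a.u., a.u.)`.
#' @return a `sem_dataset` of recalibration samples (target = negated
#'   introduced aberration, relative to the autofocus baseline).
#' @export
generate_recalibration_dataset <- function(score_model, plan,
                                           optics = optics_config(),
                                           seed = 1, wd_response = 1,
                                           rotate_scan = FALSE,
                                           simplex_cfg = simplex_config(),
                                           n_patches = 10, side = 64,
                                           initial_misfocus = c(5, 1, 1)) {
  ab <- sample_aberrations(plan, seed)
  samples <- list()
  threshold <- simplex_cfg$threshold
  for (gi in seq_along(plan$groups)) {
    g <- plan$groups[[gi]]
    scene_shape <- pmax(ceiling(g$image_shape * 1.5), 192L)
    for (loc in seq_len(g$locations)) {
      scene <- scene_raster(scene_shape,
                            seed = derive_seed(seed, gi, loc, 3L),
                            blank_frac = g$blank_frac)
      acq <- acquisition_config(sigma_wd = 5, image_shape = g$image_shape,
                                dwell_time = max(g$dwell))
      scope <- virtual_scope(scene, optics, acq, wd_response = wd_response,
                             rotate_scan = rotate_scan)
      if (is.null(threshold))
        threshold <- compute_stop_threshold(scope, score_model,
                                            n_patches = n_patches,
                                            side = side,
                                            seed = derive_seed(seed, 17L))
      cfg <- simplex_cfg
      cfg$threshold <- threshold
      cfg$seed <- derive_seed(seed, gi, loc, 5L)
      mis <- with_seed(derive_seed(seed, gi, loc, 4L),
                       stats::runif(3, -initial_misfocus, initial_misfocus))
      scope_set_state(scope, focus_state(mis[1], mis[2], mis[3]))
      af <- nelder_mead_autofocus(scope, score_model, cfg, n_patches, side,
                                  score_seed = derive_seed(seed, gi, loc, 6L))
      if (!af$converged) {
        warning(sprintf("autofocus did not converge at location %d/%d; skipped",
                        gi, loc))
        next
      }
      baseline <- scope_true_state(scope)
      rows <- which(ab$group == gi & ab$location == loc)
      for (k in seq_along(rows)) {
        r <- rows[k]
        dwell <- if (length(g$dwell) > 1L) {
          with_seed(derive_seed(seed, gi, loc, k, 7L), sample(g$dwell, 1L))
        } else g$dwell
        st <- focus_state(baseline[[1]] + ab$wd[r],
                          baseline[[2]] + ab$stig_x[r],
                          baseline[[3]] + ab$stig_y[r])
        scope_set_state(scope, st)
        pair <- scope_acquire_pair(scope,
                                   seed = derive_seed(seed, gi, loc, k, 8L),
                                   dwell_time = dwell)
        storage.mode(pair$minus) <- "integer"
        storage.mode(pair$plus) <- "integer"
        samples[[length(samples) + 1L]] <- list(
          pair = pair,
          target = focus_state(-ab$wd[r], -ab$stig_x[r], -ab$stig_y[r]),
          meta = list(group = gi, location = loc, dwell = dwell,
                      image_shape = g$image_shape, sigma_wd = acq$sigma_wd,
                      baseline = as.numeric(baseline)))
      }
    }
  }
  structure(list(samples = samples, plan = plan, seed = seed),
            class = "sem_dataset")
}
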