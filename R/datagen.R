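#' Define a ground-truth sampling plan
#'
#' A plan is one or more location groups; each group states how many
#' distinct scenes (locations) to visit, how many aberrations to introduce
#' per location, the uniform sampling ranges, the acquired image shape and
#' the dwell-time options (one is drawn per sample when several are given).
#'
#' @param locations number of distinct scenes.
#' @param aberrations_per_location introduced aberrations per scene.
#' @param wd_range working-distance bound, um (components drawn uniformly
#'   in `[-wd_range, wd_range]`).
#' @param stig_range stigmator bound, a.u.
#' @param image_shape `c(rows, cols)` of the acquired rasters.
#' @param dwell dwell-time options, ns.
#' @param blank_frac blank-ellipse area fraction of the generated scenes.
#' @return a list of class `sampling_plan` with one group.
#' @export
sampling_plan <- function(locations, aberrations_per_location = 10,
                          wd_range = 20, stig_range = 5,
                          image_shape = c(128, 128), dwell = 200,
                          blank_frac = 0.1) {
  stopifnot(locations >= 1, aberrations_per_location >= 1,
            wd_range > 0, stig_range > 0)
  structure(list(groups = list(list(
    locations = as.integer(locations),
    aberrations_per_location = as.integer(aberrations_per_location),
    wd_range = wd_range, stig_range = stig_range,
    image_shape = as.integer(image_shape), dwell = dwell,
    blank_frac = blank_frac
  ))), class = "sampling_plan")
}

#' Concatenate sampling-plan groups
#'
#' @param ... `sampling_plan` objects.
#' @return a combined `sampling_plan`.
#' @export
combine_plans <- function(...) {
  plans <- list(...)
  structure(list(groups = do.call(c, lapply(plans, `[[`, "groups"))),
            class = "sampling_plan")
}

plan_size <- function(plan) {
  sum(vapply(plan$groups,
             function(g) g$locations * g$aberrations_per_location, 0))
}

#' The original two-group ground-truth plan at desk scale
#'
#' 23 locations with tight stigmator sampling plus 17 locations with the
#' wide ranges, 10 aberrations each (400 samples). Image shapes are the
#' instrument shapes scaled to desk size (1/8 per side) so the full
#' pipeline runs in seconds; counts and split arithmetic are unchanged.
#'
#' @return a `sampling_plan`.
#' @export
reference_ground_truth_plan <- function() {
  combine_plans(
    sampling_plan(23, 10, wd_range = 20, stig_range = 0.5,
                  image_shape = c(96, 128)),
    sampling_plan(17, 10, wd_range = 20, stig_range = 5,
                  image_shape = c(192, 256))
  )
}

#' The recalibration acquisition plan at desk scale
#'
#' 10 grid locations, 10 aberrations each (100 samples), uniform within
#' +/-20 um and +/-5 a.u., dwell drawn as 200 or 100 ns per image.
#'
#' @return a `sampling_plan`.
#' @export
recalibration_plan <- function() {
  sampling_plan(10, 10, wd_range = 20, stig_range = 5,
                image_shape = c(128, 128), dwell = c(200, 100))
}

#' Sample aberration vectors according to a plan
#'
#' Every component is drawn uniformly within its group's range;
#' deterministic given `seed`.
#'
#' @param plan a [sampling_plan()].
#' @param seed integer seed.
#' @return a data frame with columns `group`, `location`, `wd`, `stig_x`,
#'   `stig_y`; one row per location-aberration pair.
#' @export
sample_aberrations <- function(plan, seed = 1) {
  rows <- list()
  for (gi in seq_along(plan$groups)) {
    g <- plan$groups[[gi]]
    n <- g$locations * g$aberrations_per_location
    ab <- with_seed(derive_seed(seed, gi), data.frame(
      group = gi,
      location = rep(seq_len(g$locations), each = g$aberrations_per_location),
      wd = stats::runif(n, -g$wd_range, g$wd_range),
      stig_x = stats::runif(n, -g$stig_range, g$stig_range),
      stig_y = stats::runif(n, -g$stig_range, g$stig_range)
    ))
    rows[[gi]] <- ab
  }
  do.call(rbind, rows)
}

#' Generate a ground-truth dataset on the virtual microscope
#'
#' For every location a fresh scene is rendered (the zero-aberration state
#' is the sharp baseline by construction), each sampled aberration is
#' introduced, and a +/-`sigma_wd` perturbed pair is acquired. Each stored
#' sample carries the pair and the *negated* aberration as its target — the
#' correction that restores focus.
#'
#' @param plan a [sampling_plan()].
#' @param optics an [optics_config()].
#' @param seed integer seed; scenes, aberrations and noise all derive from it.
#' @param sigma_wd perturbation magnitude, um.
#' @param scene_margin scenes are rendered at least this factor larger than
#'   the image shape (and at least 192 px) so large-defocus kernels fit.
#' @return an object of class `sem_dataset`.
#' @export
generate_ground_truth <- function(plan, optics = optics_config(), seed = 1,
                                  sigma_wd = 5, scene_margin = 1.5) {
  ab <- sample_aberrations(plan, seed)
  samples <- vector("list", nrow(ab))
  si <- 0L
  for (gi in seq_along(plan$groups)) {
    g <- plan$groups[[gi]]
    scene_shape <- pmax(ceiling(g$image_shape * scene_margin), 192L)
    for (loc in seq_len(g$locations)) {
      scene <- scene_raster(scene_shape, seed = derive_seed(seed, gi, loc),
                            blank_frac = g$blank_frac)
      rows <- which(ab$group == gi & ab$location == loc)
      for (k in seq_along(rows)) {
        r <- rows[k]
        si <- si + 1L
        dwell <- if (length(g$dwell) > 1L) {
          with_seed(derive_seed(seed, gi, loc, k, 7L),
                    sample(g$dwell, 1L))
        } else g$dwell
        acq <- acquisition_config(sigma_wd = sigma_wd,
                                  image_shape = g$image_shape,
                                  dwell_time = dwell)
        st <- focus_state(ab$wd[r], ab$stig_x[r], ab$stig_y[r])
        pair <- acquire_perturbed_pair(scene, st, acq, optics,
                                       seed = derive_seed(seed, gi, loc, k))
        storage.mode(pair$minus) <- "integer"
        storage.mode(pair$plus) <- "integer"
        samples[[si]] <- list(
          pair = pair,
          target = focus_state(-ab$wd[r], -ab$stig_x[r], -ab$stig_y[r]),
          meta = list(group = gi, location = loc, dwell = dwell,
                      image_shape = g$image_shape, sigma_wd = sigma_wd)
        )
      }
    }
  }
  structure(list(samples = samples, plan = plan, seed = seed),
            class = "sem_dataset")
}

#' @export
length.sem_dataset <- function(x) length(x$samples)

#' @export
print.sem_dataset <- function(x, ...) {
  cat(sprintf("<sem_dataset> %d samples\n", length(x$samples)))
  invisible(x)
}

subset_dataset <- function(dataset, idx) {
  structure(list(samples = dataset$samples[idx], plan = dataset$plan,
                 seed = dataset$seed), class = "sem_dataset")
}

#' Shuffle and split a dataset into training and validation sets
#'
#' Samples (not locations) are shuffled before splitting, so a location's
#' aberrations can appear in both sets. The split is disjoint and exhaustive
#' and `|train| = round(fraction * n)`.
#'
#' @param dataset a `sem_dataset`.
#' @param fraction training fraction (default 0.8).
#' @param seed shuffle seed.
#' @return a list of class `dataset_split` with elements `train` and
#'   `validation` (both `sem_dataset`), `fraction`, `seed`.
#' @export
split_dataset <- function(dataset, fraction = 0.8, seed = 1) {
  n <- length(dataset$samples)
  ord <- with_seed(seed, sample.int(n))
  n_train <- round(fraction * n)
  structure(list(train = subset_dataset(dataset, ord[seq_len(n_train)]),
                 validation = subset_dataset(dataset, ord[-seq_len(n_train)]),
                 fraction = fraction, seed = seed),
            class = "dataset_split")
}

#' Crop random patch pairs from a perturbed image pair
#'
#' Offsets are uniform over all valid top-left corners (0-based). With
#' `shared_offset = TRUE` both crops of a pair use the same offset (the
#' standard convention); otherwise the two offsets are drawn independently.
#'
#' @param pair a `perturbed_pair` (or any list with `minus`/`plus` rasters).
#' @param n number of patch pairs.
#' @param side patch side, pixels.
#' @param shared_offset logical.
#' @param seed integer seed.
#' @return a list of `n` patch pairs, each with `minus`, `plus`,
#'   `offset_minus`, `offset_plus` (`c(row, col)`, 0-based) and
#'   `shared_offset`.
#' @export
crop_patch_pairs <- function(pair, n, side, shared_offset = TRUE, seed = 1) {
  H <- nrow(pair$minus); W <- ncol(pair$minus)
  if (side > H || side > W)
    stop("patch side exceeds raster dimensions", call. = FALSE)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      o1 <- c(sample.int(H - side + 1L, 1L) - 1L,
              sample.int(W - side + 1L, 1L) - 1L)
      o2 <- if (shared_offset) o1 else
        c(sample.int(H - side + 1L, 1L) - 1L,
          sample.int(W - side + 1L, 1L) - 1L)
      list(minus = pair$minus[o1[1] + seq_len(side), o1[2] + seq_len(side)],
           plus = pair$plus[o2[1] + seq_len(side), o2[2] + seq_len(side)],
           offset_minus = o1, offset_plus = o2,
           shared_offset = shared_offset)
    })
  })
}

#' Rescale gray levels to the model input range
#'
#' Affine map from `[0, 255]` to `[-1, 1]`: `v / 127.5 - 1`.
#'
#' @param raster numeric matrix or array with values in `[0, 255]`.
#' @return the rescaled object.
#' @export
normalize_intensity <- function(raster) {
  if (any(raster < 0 | raster > 255))
    stop("intensities must lie in [0, 255]", call. = FALSE)
  raster / 127.5 - 1
}

#' Save a dataset container
#'
#' One self-contained file per dataset (sample images, targets, metadata
#' and the generating plan), written with serialization version 3 so that
#' a reload compares bit-exactly.
#'
#' @param dataset a `sem_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_dataset <- function(dataset, path) {
  saveRDS(dataset, path, version = 3)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) readRDS(path)
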