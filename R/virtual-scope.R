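#' Focus state of the (virtual) microscope
#'
#' The controllable triple: working-distance offset from the nominal sharp
#' setting (micrometres) and the two stigmator controls (instrument
#' arbitrary units). The same representation is used for aberration vectors
#' (deviations from the sharp baseline) and for correction estimates; the
#' negation of an aberration is the ideal correction.
#'
#' @param wd working distance offset, um.
#' @param stig_x on-axis stigmator, a.u.
#' @param stig_y diagonal stigmator, a.u.
#' @return a named numeric vector of class `focus_state`.
#' @export
focus_state <- function(wd = 0, stig_x = 0, stig_y = 0) {
  x <- c(wd = as.numeric(wd), stig_x = as.numeric(stig_x),
         stig_y = as.numeric(stig_y))
  stopifnot_finite(x, "focus state")
  class(x) <- "focus_state"
  x
}

as_focus_state <- function(x) {
  if (inherits(x, "focus_state")) return(x)
  x <- as.numeric(x)
  stopifnot(length(x) == 3L)
  focus_state(x[1], x[2], x[3])
}

#' @export
print.focus_state <- function(x, ...) {
  cat(sprintf("<focus_state> wd=%.4g um, stig_x=%.4g, stig_y=%.4g\n",
              x[1], x[2], x[3]))
  invisible(x)
}

#' Optical constants of the virtual microscope
#'
#' The beam-spot forward model is an anisotropic Gaussian with two line
#' foci: principal-axis widths `sigma0 + |k_d*wd + k_s*a|` and
#' `sigma0 + |k_d*wd - k_s*a|` where `a` is the stigmator magnitude. Pure
#' defocus blurs isotropically; pure astigmatism blurs along one axis on
#' either side of focus, flipping direction with the sign of the defocus.
#' Zero aberration is the unique sharpness optimum.
#'
#' @param sigma0 residual spot size at perfect focus, pixels.
#' @param k_d blur growth per micrometre of defocus, px/um.
#' @param k_s blur growth per arbitrary unit of astigmatism, px/a.u.
#' @param dose_per_dwell expected electrons per pixel per nanosecond of
#'   dwell at full intensity (gray level 255). The default of 10 makes a
#'   50 ns dwell correspond to roughly 5 electrons/nm^2 and 200 ns to
#'   roughly 20 electrons/nm^2 at 10 nm pixels.
#' @param read_noise_sd additive Gaussian read noise, gray levels.
#' @return a list of class `optics_config`.
#' @export
optics_config <- function(sigma0 = 0.6, k_d = 0.5, k_s = 0.5,
                          dose_per_dwell = 10, read_noise_sd = 2) {
  stopifnot(sigma0 > 0, k_d > 0, k_s > 0, dose_per_dwell > 0,
            read_noise_sd >= 0)
  structure(list(sigma0 = sigma0, k_d = k_d, k_s = k_s,
                 dose_per_dwell = dose_per_dwell,
                 read_noise_sd = read_noise_sd),
            class = "optics_config")
}

#' Acquisition settings
#'
#' @param sigma_wd symmetric working-distance perturbation used for the
#'   two-image acquisition, um (default 5).
#' @param image_shape `c(rows, cols)` of acquired rasters.
#' @param dwell_time beam dwell per pixel, ns.
#' @param pixel_size pixel size, nm.
#' @return a list of class `acquisition_config`.
#' @export
acquisition_config <- function(sigma_wd = 5, image_shape = c(128, 128),
                               dwell_time = 200, pixel_size = 10) {
  stopifnot(sigma_wd > 0, length(image_shape) == 2L, all(image_shape >= 1),
            dwell_time > 0, pixel_size > 0)
  structure(list(sigma_wd = sigma_wd,
                 image_shape = as.integer(image_shape),
                 dwell_time = dwell_time, pixel_size = pixel_size),
            class = "acquisition_config")
}

#' Beam-spot convolution kernel for a focus state
#'
#' Builds the normalized anisotropic Gaussian point-spread function of the
#' two-line-foci model: principal widths
#' `sigma_u = sigma0 + |k_d*wd + k_s*a|`, `sigma_v = sigma0 + |k_d*wd - k_s*a|`
#' with `a = sqrt(stig_x^2 + stig_y^2)`, axes rotated by
#' `theta = atan2(stig_y, stig_x) / 2`. Support is truncated at four times
#' the larger width.
#'
#' @param state a [focus_state()].
#' @param optics an [optics_config()].
#' @param max_radius optional cap on the support radius, pixels (the
#'   kernel is renormalized after truncation).
#' @return a numeric matrix summing to 1.
#' @export
beam_spot_kernel <- function(state, optics, max_radius = Inf) {
  state <- as_focus_state(state)
  stopifnot_finite(unclass(state), "focus state")
  a <- sqrt(state[["stig_x"]]^2 + state[["stig_y"]]^2)
  theta <- 0.5 * atan2(state[["stig_y"]], state[["stig_x"]])
  su <- optics$sigma0 + abs(optics$k_d * state[["wd"]] + optics$k_s * a)
  sv <- optics$sigma0 + abs(optics$k_d * state[["wd"]] - optics$k_s * a)
  r <- min(max(1L, ceiling(4 * max(su, sv))), max_radius)
  g <- seq(-r, r)
  yy <- matrix(g, 2 * r + 1, 2 * r + 1)           # row offsets (y)
  xx <- t(yy)                                     # column offsets (x)
  u <- cos(theta) * xx + sin(theta) * yy
  v <- -sin(theta) * xx + cos(theta) * yy
  k <- exp(-0.5 * (u / su)^2 - 0.5 * (v / sv)^2)
  k / sum(k)
}

# Circular convolution of a scene with a (smaller) kernel via FFT. Scenes
# generated by scene_raster() are periodic, so circular boundary handling is
# exact for them.
fft_convolve <- function(scene, kernel) {
  H <- nrow(scene); W <- ncol(scene)
  kh <- nrow(kernel); kw <- ncol(kernel)
  if (kh > H || kw > W)
    stop("beam kernel larger than scene; use a larger scene", call. = FALSE)
  kp <- matrix(0, H, W)
  c0 <- (kh + 1L) %/% 2L; d0 <- (kw + 1L) %/% 2L
  ri <- ((seq_len(kh) - c0) %% H) + 1L
  ci <- ((seq_len(kw) - d0) %% W) + 1L
  kp[ri, ci] <- kernel
  Re(stats::fft(stats::fft(scene) * stats::fft(kp), inverse = TRUE)) / (H * W)
}

# Poisson sampling that falls back to the normal approximation for very
# large rates (where rpois would overflow integer counts).
sample_poisson <- function(lambda) {
  out <- numeric(length(lambda))
  big <- lambda > 1e7
  if (any(!big)) out[!big] <- stats::rpois(sum(!big), lambda[!big])
  if (any(big)) out[big] <- stats::rnorm(sum(big), lambda[big], sqrt(lambda[big]))
  out
}

#' Generate a tissue-like synthetic scene
#'
#' Band-pass-filtered Gaussian random field (periodic, so virtual
#' acquisition has exact circular boundaries) with randomly placed smooth
#' ellipses of near-uniform intensity emulating low-contrast blank regions
#' such as blood vessels filled with bare resin.
#'
#' @param shape `c(rows, cols)`.
#' @param seed integer seed; the scene is a deterministic function of it.
#' @param blank_frac target area fraction covered by blank ellipses.
#' @param band passband as fractions of the sampling frequency,
#'   `c(low, high)`.
#' @param contrast_sd gray-level standard deviation of the texture.
#' @return a numeric matrix with gray values in `[0, 255]`.
#' @export
scene_raster <- function(shape = c(256, 256), seed = 1, blank_frac = 0.1,
                         band = c(0.05, 0.45), contrast_sd = 55) {
  H <- shape[1]; W <- shape[2]
  with_seed(seed, {
    z <- matrix(stats::rnorm(H * W), H, W)
    fr <- c(0:(H %/% 2), -((H - H %/% 2 - 1):1)) / H
    fc <- c(0:(W %/% 2), -((W - W %/% 2 - 1):1)) / W
    rad <- sqrt(outer(fr^2, fc^2, "+"))
    mask <- rad >= band[1] & rad <= band[2]
    zf <- stats::fft(z) * mask
    tex <- Re(stats::fft(zf, inverse = TRUE)) / (H * W)
    tex <- (tex - mean(tex)) / stats::sd(tex)
    img <- 127.5 + contrast_sd * tex
    if (blank_frac > 0) {
      covered <- 0
      target <- blank_frac * H * W
      rows <- matrix(seq_len(H), H, W)
      cols <- t(matrix(seq_len(W), W, H))
      tries <- 0L
      while (covered < target && tries < 50L) {
        tries <- tries + 1L
        cy <- stats::runif(1, 1, H); cx <- stats::runif(1, 1, W)
        ry <- stats::runif(1, 0.08, 0.22) * H
        rx <- stats::runif(1, 0.08, 0.22) * W
        phi <- stats::runif(1, 0, pi)
        dy <- rows - cy; dx <- cols - cx
        u <- cos(phi) * dx + sin(phi) * dy
        v <- -sin(phi) * dx + cos(phi) * dy
        inside <- (u / rx)^2 + (v / ry)^2 <= 1
        lvl <- stats::runif(1, 110, 150)
        img[inside] <- lvl + stats::rnorm(sum(inside), 0, 1.5)
        covered <- covered + sum(inside)
      }
    }
    pmin(pmax(img, 0), 255)
  })
}

#' Acquire a virtual SEM image
#'
#' Convolves the scene with the beam-spot kernel of `state`, converts to
#' expected electron counts (`dose_per_dwell * dwell_time`, scaled by local
#' intensity), applies Poisson shot noise and additive Gaussian read noise,
#' and rescales back to gray levels with clipping. Deterministic given
#' `seed`.
#'
#' @param scene scene raster (at least as large as `acq$image_shape`).
#' @param state a [focus_state()].
#' @param acq an [acquisition_config()].
#' @param optics an [optics_config()].
#' @param seed integer seed for the noise draw.
#' @param dwell_time optional override of `acq$dwell_time`, ns.
#' @return an integer-valued raster matrix of shape `acq$image_shape`.
#' @export
acquire <- function(scene, state, acq, optics, seed = 1, dwell_time = NULL) {
  shp <- acq$image_shape
  if (shp[1] > nrow(scene) || shp[2] > ncol(scene))
    stop("image_shape larger than scene", call. = FALSE)
  dwell <- if (is.null(dwell_time)) acq$dwell_time else dwell_time
  # support capped to the scene so extreme defocus (e.g. a diverged
  # closed-loop state) truncates the Gaussian instead of failing
  k <- beam_spot_kernel(state, optics,
                        max_radius = (min(dim(scene)) - 1L) %/% 2L)
  blurred <- fft_convolve(scene, k)[seq_len(shp[1]), seq_len(shp[2]), drop = FALSE]
  blurred <- pmin(pmax(blurred, 0), 255)
  dose <- optics$dose_per_dwell * dwell
  with_seed(seed, {
    lam <- dose * blurred / 255
    counts <- sample_poisson(lam)
    img <- counts / dose * 255
    if (optics$read_noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, optics$read_noise_sd)
    matrix(round(pmin(pmax(img, 0), 255)), shp[1], shp[2])
  })
}

#' Acquire a working-distance perturbed image pair
#'
#' Two images at `wd - sigma_wd` and `wd + sigma_wd` with stigmators
#' unchanged. The first element is always the `-sigma_wd` image; this
#' ordering is a fixed convention that trained models depend on.
#'
#' @inheritParams acquire
#' @return a list of class `perturbed_pair` with elements `minus`, `plus`,
#'   `state`, `sigma_wd`, `dwell_time`.
#' @export
acquire_perturbed_pair <- function(scene, state, acq, optics, seed = 1,
                                   dwell_time = NULL) {
  stopifnot(acq$sigma_wd > 0)
  state <- as_focus_state(state)
  s_minus <- focus_state(state[["wd"]] - acq$sigma_wd, state[["stig_x"]],
                         state[["stig_y"]])
  s_plus <- focus_state(state[["wd"]] + acq$sigma_wd, state[["stig_x"]],
                        state[["stig_y"]])
  dwell <- if (is.null(dwell_time)) acq$dwell_time else dwell_time
  structure(list(
    minus = acquire(scene, s_minus, acq, optics, derive_seed(seed, 1L), dwell),
    plus = acquire(scene, s_plus, acq, optics, derive_seed(seed, 2L), dwell),
    state = state, sigma_wd = acq$sigma_wd, dwell_time = dwell
  ), class = "perturbed_pair")
}

#' Apply a correction to a focus state
#'
#' @param state a [focus_state()].
#' @param delta a correction triple (same layout).
#' @return the componentwise sum as a [focus_state()].
#' @export
apply_correction <- function(state, delta) {
  state <- as_focus_state(state)
  delta <- as_focus_state(delta)
  focus_state(state[["wd"]] + delta[["wd"]],
              state[["stig_x"]] + delta[["stig_x"]],
              state[["stig_y"]] + delta[["stig_y"]])
}

#' Mean squared gradient sharpness of a noise-free render
#'
#' Renders the scene under `state` without noise and returns the mean
#' squared finite-difference gradient, the simulator's ground-truth
#' sharpness. Maximal at zero aberration under the two-line-foci model.
#'
#' @inheritParams acquire
#' @return scalar sharpness.
#' @export
render_sharpness <- function(scene, state, optics) {
  b <- fft_convolve(scene, beam_spot_kernel(state, optics))
  gx <- b[, -1] - b[, -ncol(b)]
  gy <- b[-1, ] - b[-nrow(b), ]
  (mean(gx^2) + mean(gy^2)) / 2
}

rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

#' Create a virtual scanning electron microscope
#'
#' Bundles a scene, optics and acquisition settings into a mutable scope
#' object exposing the acquire/apply contract a real instrument would
#' provide. The scope's internal `state` is its aberration relative to the
#' sharp baseline; control code must only ever call
#' [scope_acquire_pair()], [scope_acquire_image()] and
#' [scope_apply_correction()] — [scope_true_state()] exists solely for the
#' evaluation harness.
#'
#' `wd_response` and `rotate_scan` emulate a second instrument with a
#' reversed working-distance response and a 90-degree rotated scan, the
#' regime in which a stale model diverges and recalibration is required.
#'
#' @param scene scene raster.
#' @param optics an [optics_config()].
#' @param acq an [acquisition_config()].
#' @param wd_response `+1` or `-1`; sign of the optical response to the
#'   working-distance control.
#' @param rotate_scan logical; rotate acquired images by 90 degrees.
#' @return an environment of class `sem_scope`.
#' @export
virtual_scope <- function(scene, optics = optics_config(),
                          acq = acquisition_config(), wd_response = 1,
                          rotate_scan = FALSE) {
  stopifnot(wd_response %in% c(-1, 1))
  if (rotate_scan && acq$image_shape[1] != acq$image_shape[2])
    stop("rotated scans require square image_shape", call. = FALSE)
  sc <- new.env(parent = emptyenv())
  sc$scene <- scene
  sc$optics <- optics
  sc$acq <- acq
  sc$wd_response <- wd_response
  sc$rotate_scan <- rotate_scan
  sc$state <- focus_state(0, 0, 0)
  class(sc) <- "sem_scope"
  sc
}

effective_state <- function(scope, control_wd, sx, sy) {
  focus_state(scope$wd_response * control_wd, sx, sy)
}

#' Acquire a single image from a scope at its current state
#'
#' @param scope a [virtual_scope()].
#' @param seed integer seed.
#' @param dwell_time optional dwell override, ns.
#' @return a raster matrix.
#' @export
scope_acquire_image <- function(scope, seed = 1, dwell_time = NULL) {
  st <- scope$state
  eff <- effective_state(scope, st[["wd"]], st[["stig_x"]], st[["stig_y"]])
  img <- acquire(scope$scene, eff, scope$acq, scope$optics, seed, dwell_time)
  if (scope$rotate_scan) rot90cw(img) else img
}

#' Acquire a perturbed pair from a scope at its current state
#'
#' The perturbation is applied to the working-distance *control*; on a
#' scope with a reversed response the optical defocus ordering is therefore
#' inverted, which is precisely what breaks a stale model.
#'
#' @inheritParams scope_acquire_image
#' @return a `perturbed_pair`.
#' @export
scope_acquire_pair <- function(scope, seed = 1, dwell_time = NULL) {
  st <- scope$state
  acq <- scope$acq
  dwell <- if (is.null(dwell_time)) acq$dwell_time else dwell_time
  eff_m <- effective_state(scope, st[["wd"]] - acq$sigma_wd,
                           st[["stig_x"]], st[["stig_y"]])
  eff_p <- effective_state(scope, st[["wd"]] + acq$sigma_wd,
                           st[["stig_x"]], st[["stig_y"]])
  m <- acquire(scope$scene, eff_m, acq, scope$optics, derive_seed(seed, 1L), dwell)
  p <- acquire(scope$scene, eff_p, acq, scope$optics, derive_seed(seed, 2L), dwell)
  if (scope$rotate_scan) { m <- rot90cw(m); p <- rot90cw(p) }
  structure(list(minus = m, plus = p, state = st, sigma_wd = acq$sigma_wd,
                 dwell_time = dwell), class = "perturbed_pair")
}

#' Apply a correction to a scope
#'
#' @param scope a [virtual_scope()].
#' @param delta correction triple.
#' @return the scope, invisibly.
#' @export
scope_apply_correction <- function(scope, delta) {
  scope$state <- apply_correction(scope$state, delta)
  invisible(scope)
}

#' Set the scope aberration state directly
#'
#' @param scope a [virtual_scope()].
#' @param state a [focus_state()].
#' @return the scope, invisibly.
#' @export
scope_set_state <- function(scope, state) {
  scope$state <- as_focus_state(state)
  invisible(scope)
}

#' Read the true aberration state of a virtual scope
#'
#' Evaluation-harness accessor: returns the scope's residual aberration
#' relative to the sharp baseline. Controllers must not call this; it is
#' the simulator-side ground truth used to compute residuals.
#'
#' @param scope a [virtual_scope()].
#' @return a [focus_state()].
#' @export
scope_true_state <- function(scope) scope$state
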