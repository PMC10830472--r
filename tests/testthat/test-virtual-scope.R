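test_that("beam-spot kernel is normalized, isotropic at focus and symmetric in defocus sign", {
  opt <- default_optics()
  k0 <- beam_spot_kernel(focus_state(0, 0, 0), opt)
  expect_equal(sum(k0), 1, tolerance = 1e-6)
  # isotropic: invariant under transpose and flips
  expect_equal(k0, t(k0), tolerance = 1e-12)
  expect_equal(k0, k0[nrow(k0):1, ], tolerance = 1e-12)
  # matches a direct Gaussian with sd sigma0 (independent evaluation)
  r <- (nrow(k0) - 1L) / 2L
  g <- seq(-r, r)
  ref <- exp(-0.5 * outer(g^2, g^2, "+") / opt$sigma0^2)
  expect_equal(k0, ref / sum(ref), tolerance = 1e-12)

  # pure defocus: identical for +d and -d, wider than at focus
  kp <- beam_spot_kernel(focus_state(8, 0, 0), opt)
  km <- beam_spot_kernel(focus_state(-8, 0, 0), opt)
  expect_identical(dim(kp), dim(km))
  expect_equal(kp, km, tolerance = 1e-12)
  expect_gt(nrow(kp), nrow(k0))
  expect_equal(kp, t(kp), tolerance = 1e-12)  # still isotropic
})

kernel_axis_sds <- function(k) {
  r <- (nrow(k) - 1L) / 2L
  g <- seq(-r, r)
  cols <- matrix(g, nrow(k), ncol(k), byrow = TRUE)
  rows <- matrix(g, nrow(k), ncol(k))
  c(row = sqrt(sum(k * rows^2)), col = sqrt(sum(k * cols^2)))
}

test_that("line focus appears when defocus and astigmatism balance, and flips with defocus sign", {
  opt <- default_optics()  # k_d = k_s
  a <- 4
  kp <- beam_spot_kernel(focus_state(a, a, 0), opt)   # theta = 0
  km <- beam_spot_kernel(focus_state(-a, a, 0), opt)
  sp <- kernel_axis_sds(kp)
  sm <- kernel_axis_sds(km)
  # sigma_v = sigma0 on one side: the row (v) axis is near-residual width
  expect_lt(sp[["row"]], 1.1 * opt$sigma0)
  expect_gt(sp[["col"]], 5 * sp[["row"]])
  # flipping the defocus sign swaps the sharp axis
  expect_lt(sm[["col"]], 1.1 * opt$sigma0)
  expect_gt(sm[["row"]], 5 * sm[["col"]])
  # widths follow the two-line-foci formulas
  expect_equal(sp[["col"]], opt$sigma0 + 2 * opt$k_d * a, tolerance = 0.02)
})

test_that("rotating the stigmator vector by phi rotates the kernel axes by phi/2", {
  opt <- default_optics()
  # nonzero defocus: at perfect focus the two widths coincide for pure
  # astigmatism (|k_d*0 +/- k_s*a| are equal) and no axis is defined
  for (phi in c(pi / 3, pi / 2)) {
    k1 <- beam_spot_kernel(focus_state(2, 3, 0), opt)
    k2 <- beam_spot_kernel(focus_state(2, 3 * cos(phi), 3 * sin(phi)), opt)
    axis_angle <- function(k) {
      r <- (nrow(k) - 1L) / 2L
      g <- seq(-r, r)
      cols <- matrix(g, nrow(k), ncol(k), byrow = TRUE)
      rows <- matrix(g, nrow(k), ncol(k))
      cxx <- sum(k * cols^2); cyy <- sum(k * rows^2); cxy <- sum(k * cols * rows)
      0.5 * atan2(2 * cxy, cxx - cyy)
    }
    d <- (axis_angle(k2) - axis_angle(k1) - phi / 2) %% pi
    expect_lt(min(d, pi - d), 1e-3)
  }
  expect_equal(sum(beam_spot_kernel(focus_state(3, 2, -1),
                                    default_optics())), 1,
               tolerance = 1e-6)
})

test_that("noise-free renders depend on wd only through |wd| and are sharpest at zero aberration", {
  opt <- default_optics()
  scene <- small_scene(11)
  expect_equal(noisefree_render(scene, focus_state(6, 0, 0), opt),
               noisefree_render(scene, focus_state(-6, 0, 0), opt),
               tolerance = 1e-10)
  s0 <- render_sharpness(scene, focus_state(0, 0, 0), opt)
  for (wd in c(-8, -3, 3, 8))
    for (sx in c(-3, 0, 3)) {
      if (wd == 0 && sx == 0) next
      expect_lt(render_sharpness(scene, focus_state(wd, sx, 0), opt), s0)
      expect_lt(render_sharpness(scene, focus_state(wd, 0, sx), opt), s0)
    }
})

test_that("acquisition is deterministic, converges to the blurred scene at high dose, and noise scales with dwell", {
  opt <- default_optics()
  scene <- small_scene(3)
  acq <- small_acq(c(96, 96))
  a1 <- acquire(scene, focus_state(2, 1, 0), acq, opt, seed = 5)
  a2 <- acquire(scene, focus_state(2, 1, 0), acq, opt, seed = 5)
  expect_identical(a1, a2)
  a3 <- acquire(scene, focus_state(2, 1, 0), acq, opt, seed = 6)
  expect_false(identical(a1, a3))

  # infinite-dose limit: no read noise, huge dwell -> sigma0-blurred scene
  opt0 <- optics_config(read_noise_sd = 0)
  hi <- acquire(scene, focus_state(0, 0, 0), acq, opt0, seed = 1,
                dwell_time = 1e7)
  ref <- noisefree_render(scene, focus_state(0, 0, 0), opt0)[1:96, 1:96]
  expect_lt(max(abs(hi - ref)), 1)

  # Poisson shot noise: variance ratio ~ dose ratio (16x) on a flat scene
  flat <- matrix(127.5, 192, 192)
  v50 <- var(as.vector(acquire(flat, focus_state(0, 0, 0), acq, opt0,
                               seed = 2, dwell_time = 50)))
  v800 <- var(as.vector(acquire(flat, focus_state(0, 0, 0), acq, opt0,
                                seed = 3, dwell_time = 800)))
  expect_equal(v50 / v800, 16, tolerance = 0.15)
})

test_that("perturbed pairs use the fixed (-sigma, +sigma) ordering", {
  opt <- default_optics()
  scene <- small_scene(7)
  acq <- small_acq(c(96, 96))
  # at wd = +sigma_wd the first image is in focus, the second at 2*sigma
  pair <- acquire_perturbed_pair(scene, focus_state(acq$sigma_wd, 0, 0),
                                 acq, opt, seed = 4)
  grad_energy <- function(m) mean(diff(m)^2) + mean(t(diff(t(m)))^2)
  expect_gt(grad_energy(pair$minus), 2 * grad_energy(pair$plus))
  # symmetric about focus: equal blur at wd = 0
  pair0 <- acquire_perturbed_pair(scene, focus_state(0, 0, 0), acq, opt,
                                  seed = 4)
  expect_equal(grad_energy(pair0$minus) / grad_energy(pair0$plus), 1,
               tolerance = 0.05)
  expect_error(acquire(scene, focus_state(0, 0, 0),
                       small_acq(c(500, 500)), opt),
               "larger than scene")
})

test_that("corrections add componentwise and states validate", {
  expect_equal(as.numeric(apply_correction(focus_state(30, 6, -6),
                                           c(-30, -6, 6))),
               c(0, 0, 0))
  st <- focus_state(8, -3, 3)
  expect_equal(as.numeric(apply_correction(st, c(0, 0, 0))),
               as.numeric(st))
  expect_equal(as.numeric(apply_correction(st, c(-7.5, 2.8, -2.9))),
               c(0.5, -0.2, 0.1), tolerance = 1e-12)
  expect_error(focus_state(NaN, 0, 0), "non-finite")
  expect_error(beam_spot_kernel(focus_state(0, 0, 0),
                                optics_config(sigma0 = -1)))
})

test_that("scope objects expose the acquire/apply contract and emulate a modified instrument", {
  opt <- default_optics()
  scene <- small_scene(9, shape = c(192, 192))
  acq <- small_acq(c(96, 96))
  scope <- virtual_scope(scene, opt, acq)
  scope_set_state(scope, focus_state(5, 1, -1))
  scope_apply_correction(scope, c(-5, -1, 1))
  expect_equal(as.numeric(scope_true_state(scope)), c(0, 0, 0))

  # reversed wd response: with astigmatism present, the image at control
  # state (w, s) matches the normal scope's image at (-w, s) — a pure
  # magnitude flip is invisible without the astigmatic coupling
  scope_b <- virtual_scope(scene, opt, acq, wd_response = -1)
  scope_a <- virtual_scope(scene, opt, acq)
  scope_set_state(scope_b, focus_state(4, 2, 0))
  scope_set_state(scope_a, focus_state(-4, 2, 0))
  expect_identical(scope_acquire_image(scope_b, seed = 2),
                   scope_acquire_image(scope_a, seed = 2))
  scope_set_state(scope_a, focus_state(4, 2, 0))
  expect_false(identical(scope_acquire_image(scope_b, seed = 2),
                         scope_acquire_image(scope_a, seed = 2)))

  # rotated scan: image is the 90-degree rotation of the unrotated one
  sc1 <- virtual_scope(scene, opt, acq)
  sc2 <- virtual_scope(scene, opt, acq, rotate_scan = TRUE)
  i1 <- scope_acquire_image(sc1, seed = 3)
  i2 <- scope_acquire_image(sc2, seed = 3)
  expect_identical(i2, t(i1[nrow(i1):1, ]))
})

test_that("rasters round-trip through 8-bit TIFF", {
  img <- matrix(round(seq(0, 255, length.out = 64 * 48)), 48, 64)
  path <- tempfile(fileext = ".tif")
  write_raster(img, path)
  back <- read_raster(path)
  expect_equal(back, img, ignore_attr = TRUE)
  unlink(path)
})
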