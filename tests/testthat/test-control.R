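# Oracle controllers: functions of (pair, patches) closing over the scope
# or over the pair's acquisition state (the introduced aberration).

perfect_oracle <- function(scope) {
  function(pair, patches) -as.numeric(scope_true_state(scope))
}

contraction_oracle <- function(scope, c = 0.9) {
  function(pair, patches) -c * as.numeric(scope_true_state(scope))
}

test_that("a perfect oracle converges in exactly one iteration from any initial aberration", {
  scene <- small_scene(21)
  scope <- virtual_scope(scene, default_optics(), small_acq(c(96, 96)))
  cfg <- control_config(n_patches = 2, patch_side = 64, max_iter = 3)
  for (init in list(c(30, 6, -6), c(-12, 1, 4), c(0, 0, 0))) {
    rec <- run_autofocus(scope, perfect_oracle(scope), cfg,
                         focus_state(init[1], init[2], init[3]), seed = 1)
    tr <- rec$trajectory
    expect_equal(unname(unlist(tr[tr$iteration >= 1,
                                  c("d_wd", "d_stig_x", "d_stig_y")])),
                 rep(0, 9), tolerance = 1e-12)
    expect_lte(convergence_iteration(rec), 1)
  }
})

test_that("a contraction oracle shrinks residuals geometrically", {
  scene <- small_scene(22)
  scope <- virtual_scope(scene, default_optics(), small_acq(c(96, 96)))
  cfg <- control_config(n_patches = 2, patch_side = 64, max_iter = 4)
  init <- c(20, 4, -4)
  rec <- run_autofocus(scope, contraction_oracle(scope, 0.9), cfg,
                       focus_state(init[1], init[2], init[3]), seed = 1)
  tr <- rec$trajectory
  for (k in 0:4) {
    expect_equal(unname(unlist(tr[tr$iteration == k,
                                  c("d_wd", "d_stig_x", "d_stig_y")])),
                 0.1^k * abs(init), tolerance = 1e-9)
  }
})

test_that("residuals are absolute componentwise differences", {
  expect_equal(unname(residual(c(1, 2, 3), c(1, 2, 3))), c(0, 0, 0))
  expect_equal(unname(residual(c(-29, 5.5, -6.2), c(-30, 6, -6))),
               c(1, 0.5, 0.2), tolerance = 1e-12)
  expect_equal(residual(c(1, -2, 0.5), c(-3, 4, 2)),
               residual(c(-3, 4, 2), c(1, -2, 0.5)))
})

test_that("ordinary least squares recovers the response line", {
  # identity response
  x <- c(-20, -10, -5, -2, -1, 1, 2, 5, 10, 20)
  f <- fit_linearity(x, x)
  expect_equal(f$c1, 1, tolerance = 1e-12)
  expect_equal(f$c2, 0, tolerance = 1e-12)
  # noiseless synthetic response with the reference coefficients is
  # recovered to machine precision
  y <- 0.9093 * x + 0.3436
  f2 <- fit_linearity(x, y)
  expect_equal(f2$c1, 0.9093, tolerance = 1e-12)
  expect_equal(f2$c2, 0.3436, tolerance = 1e-12)
  expect_lt(f2$se_c1, 1e-12)
  expect_error(fit_linearity(c(1, 1, 1), c(1, 2, 3)), "degenerate")
  expect_error(fit_linearity(c(1, 2), c(1, 2)), "at least 3")
})

test_that("single-iteration MAE evaluation matches direct computation", {
  ds <- tiny_dataset()
  targets <- t(vapply(ds$samples, function(s) as.numeric(s$target),
                      numeric(3)))
  # an oracle reading the pair's acquisition state has zero error
  oracle <- function(pair, patches) -as.numeric(pair$state)
  ev0 <- evaluate_mae(oracle, ds, n_patches = 1, side = 64, seed = 1)
  expect_equal(unname(ev0$mae), c(0, 0, 0), tolerance = 1e-12)
  # the constant-zero model's MAE is the mean absolute target
  zero <- function(pair, patches) c(0, 0, 0)
  evz <- evaluate_mae(zero, ds, n_patches = 1, side = 64, seed = 1)
  expect_equal(unname(evz$mae), unname(colMeans(abs(targets))),
               tolerance = 1e-12)
  expect_equal(unname(evz$sd), unname(apply(abs(targets), 2, sd)),
               tolerance = 1e-12)
})

test_that("smaller residuals mean images closer to the in-focus render", {
  opt <- default_optics()
  scene <- small_scene(31)
  ref <- noisefree_render(scene, focus_state(0, 0, 0), opt)
  wds <- c(0.5, 1, 2, 4, 8, 12)
  sims <- vapply(wds, function(w)
    ssim(ref, noisefree_render(scene, focus_state(w, 0.2 * w, 0), opt)), 0)
  mses <- vapply(wds, function(w)
    mean((ref - noisefree_render(scene, focus_state(w, 0.2 * w, 0),
                                 opt))^2), 0)
  # rank correlation: larger residual aberration, lower similarity
  expect_gt(cor(wds, -sims, method = "spearman"), 0)
  expect_gt(cor(wds, mses, method = "spearman"), 0)
  expect_equal(ssim(ref, ref), 1, tolerance = 1e-12)
})

test_that("trajectories export to CSV with residual columns", {
  scene <- small_scene(23)
  scope <- virtual_scope(scene, default_optics(), small_acq(c(96, 96)))
  rec <- run_autofocus(scope, perfect_oracle(scope),
                       control_config(n_patches = 1, patch_side = 64,
                                      max_iter = 2),
                       focus_state(10, 2, -2), seed = 1)
  path <- tempfile(fileext = ".csv")
  write_trajectory(rec, path)
  back <- read.csv(path)
  expect_identical(nrow(back), 3L)
  expect_true(all(c("iteration", "wd", "stig_x", "stig_y", "d_wd",
                    "d_stig_x", "d_stig_y") %in% names(back)))
  unlink(path)
})
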