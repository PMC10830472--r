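test_that("layer-chain arithmetic reproduces every printed head size", {
  s2 <- stacked_conv_spec()
  expect_identical(conv_stack_feature_dim(s2, 512, 2), 6860L)
  expect_identical(conv_stack_feature_dim(s2, 384, 2), 3500L)
  expect_identical(conv_stack_feature_dim(s2, 256, 2), 1260L)
  expect_identical(conv_stack_feature_dim(s2, 128, 2), 140L)
  s3 <- deepscore_conv_spec()
  expect_identical(conv_stack_feature_dim(s3, 512, 1), 2520L)
  # a two-image input would need 5040 features, contradicting the printed
  # 2520: the score model consumes a single image
  expect_identical(conv_stack_feature_dim(s3, 512, 2), 5040L)
  # identity chain: one 1x1 conv with pool 1 preserves side
  ident <- encoder_spec(out_ch = 9L, kernel = 1L, pool = 1L)
  expect_equal(conv_stack_feature_dim(ident, 21, 2), 9 * 2 * 21^2)
  # seven-layer chain collapses below 128 px
  expect_error(conv_stack_feature_dim(s2, 64, 2), "collapses")
})

test_that("correction models are built with the matching fully connected chain", {
  m512 <- build_correction_model(stacked_conv_spec(), 512, 3, seed = 1)
  fcs <- Filter(function(l) l$type == "fc", m512$layers)
  expect_equal(vapply(fcs, function(l) dim(l$params$W), integer(2)),
               cbind(c(6860L, 250L), c(250L, 50L), c(50L, 3L)))
  m128 <- build_correction_model(stacked_conv_spec(), 128, 3, seed = 1)
  fcs <- Filter(function(l) l$type == "fc", m128$layers)
  expect_equal(vapply(fcs, function(l) dim(l$params$W), integer(2)),
               cbind(c(140L, 100L), c(100L, 50L), c(50L, 3L)))
  sc <- build_deepscore_model(deepscore_conv_spec(), 512, seed = 1)
  fcs <- Filter(function(l) l$type == "fc", sc$layers)
  expect_equal(vapply(fcs, function(l) dim(l$params$W), integer(2)),
               cbind(c(2520L, 250L), c(250L, 50L), c(50L, 2L)))
})

test_that("untrained models produce finite outputs of the declared arity", {
  m3 <- build_correction_model(desk_conv_spec(), 64, 3, seed = 2)
  m4 <- build_correction_model(desk_conv_spec(), 64, 4, seed = 2)
  p <- list(minus = matrix(runif(64^2, 0, 255), 64),
            plus = matrix(runif(64^2, 0, 255), 64))
  r3 <- predict_corrections(m3, list(p))
  expect_identical(dim(r3$estimates), c(1L, 3L))
  expect_true(all(is.finite(r3$estimates)))
  expect_null(r3$scores)
  r4 <- predict_corrections(m4, list(p, p))
  expect_identical(dim(r4$estimates), c(2L, 3L))
  expect_length(r4$scores, 2L)
  ds <- build_deepscore_model(desk_score_spec(), 64, seed = 3)
  rs <- predict_sharpness(ds, list(p$minus))
  expect_identical(dim(rs), c(1L, 2L))
  expect_true(all(is.finite(rs)))
})

test_that("batched evaluation equals sequential evaluation and shares weights across the pair", {
  m <- build_correction_model(desk_conv_spec(), 64, 3, seed = 4)
  set.seed(10)
  ps <- lapply(1:3, function(i)
    list(minus = matrix(runif(64^2, 0, 255), 64),
         plus = matrix(runif(64^2, 0, 255), 64)))
  batch <- predict_corrections(m, ps)$estimates
  seq_est <- do.call(rbind, lapply(ps, function(p)
    predict_corrections(m, list(p))$estimates))
  expect_equal(batch, seq_est, tolerance = 1e-12)
  # permuting the batch permutes the rows and nothing else
  perm <- predict_corrections(m, ps[c(3, 1, 2)])$estimates
  expect_equal(perm, batch[c(3, 1, 2), ], tolerance = 1e-12)
  # weight sharing: identical image slices give identical conv features
  x <- semfocus:::patches_to_tensor(list(list(minus = ps[[1]]$minus,
                                              plus = ps[[1]]$minus)), 2L)
  feat <- x
  for (l in m$layers) {
    if (l$type != "conv_block") break
    feat <- semfocus:::layer_forward(l, feat, training = FALSE)$y
  }
  expect_equal(feat[, , , 1], feat[, , , 2], tolerance = 1e-12)
})

test_that("softmax weighting reduces scored estimates inside their convex hull", {
  est <- rbind(c(1, 0, -1), c(3, 2, 0), c(-2, 1, 4))
  # equal scores: plain mean
  expect_equal(as.numeric(weighted_correction(est, c(2, 2, 2))),
               colMeans(est))
  # singleton passes through
  expect_equal(as.numeric(weighted_correction(est[1, , drop = FALSE], 5)),
               est[1, ])
  # dominant score: matches direct softmax evaluation
  w <- exp(c(10, 0, 0) - 10); w <- w / sum(w)
  expect_equal(as.numeric(weighted_correction(est, c(10, 0, 0))),
               as.numeric(colSums(est * w)), tolerance = 1e-12)
  expect_lt(max(abs(as.numeric(weighted_correction(est, c(10, 0, 0))) -
                    est[1, ])), 1e-3)
  # extreme scores stay numerically stable
  expect_true(all(is.finite(weighted_correction(est, c(1e4, 0, -1e4)))))
  # convex hull property over random cases
  set.seed(42)
  for (i in 1:25) {
    e <- matrix(rnorm(15), 5, 3)
    s <- rnorm(5, sd = 3)
    v <- as.numeric(weighted_correction(e, s))
    expect_true(all(v >= apply(e, 2, min) - 1e-12))
    expect_true(all(v <= apply(e, 2, max) + 1e-12))
  }
  # list-of-scored-corrections interface
  preds <- list(list(estimate = c(1, 0, 0), score = 0),
                list(estimate = c(3, 0, 0), score = 0))
  expect_equal(as.numeric(weighted_correction(preds)), c(2, 0, 0))
  expect_error(weighted_correction(matrix(0, 0, 3), numeric(0)), "no pred")
})

test_that("plain mean reduction is componentwise arithmetic", {
  expect_equal(as.numeric(reduce_plain_mean(rbind(c(1, 2, 3), c(1, 2, 3)))),
               c(1, 2, 3))
  expect_equal(as.numeric(reduce_plain_mean(rbind(c(1, 0, 0), c(-1, 0, 0)))),
               c(0, 0, 0))
  e <- rbind(c(0.3, -1, 2), c(4, 0.5, -3), c(-1, 1, 1))
  expect_equal(as.numeric(reduce_plain_mean(e)),
               as.numeric(colSums(e) / 3), tolerance = 1e-12)
  expect_error(reduce_plain_mean(matrix(0, 0, 3)), "no pred")
})

test_that("checkpoints reload to bit-identical models with a JSON sidecar", {
  m <- build_correction_model(desk_conv_spec(), 64, 4, seed = 6)
  p <- list(minus = matrix(runif(64^2, 0, 255), 64),
            plus = matrix(runif(64^2, 0, 255), 64))
  before <- predict_corrections(m, list(p))
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  back <- load_model(path)
  after <- predict_corrections(back, list(p))
  expect_identical(after, before)
  sidecar <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(sidecar$input_side, 64)
  expect_equal(sidecar$outputs, 4)
  expect_match(sidecar$normalization, "-1")
  unlink(c(path, paste0(path, ".json")))
})

test_that("the pixel-score U-Net yields 4 channels per pixel and enforces the pooling constraint", {
  um <- build_pixel_score_model(start_filters = 8L, seed = 5)
  p <- list(minus = matrix(runif(32^2, 0, 255), 32),
            plus = matrix(runif(32^2, 0, 255), 32))
  r <- predict_dense(um, list(p))
  expect_identical(dim(r$maps[[1]]), c(32L, 32L, 4L))
  expect_true(all(is.finite(r$maps[[1]])))
  expect_identical(dim(r$estimates), c(1L, 3L))
  bad <- list(minus = matrix(0, 20, 20), plus = matrix(0, 20, 20))
  expect_error(predict_dense(um, list(bad)), "divisible by 8")
  # uniform score field: the weighted average equals the plain spatial mean
  um0 <- um
  um0$layers$h2$params$W[, 4] <- 0
  um0$layers$h2$params$b[4] <- 0
  r0 <- predict_dense(um0, list(p))
  expect_equal(as.numeric(r0$estimates),
               apply(r0$maps[[1]][, , 1:3], 3, mean), tolerance = 1e-10)
})
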