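# Pixel-level scoring model: a planar U-Net applied with shared weights to
# the two images of a pair (slices of the batch dimension), whose final
# per-image channels are concatenated and projected to 4 channels per pixel
# (3 correction components + 1 unnormalized score). Same-padding
# convolutions, group normalization, nearest-resize + convolution
# upsampling.

gnconv_unit <- function(in_ch, out_ch, kernel = 3L, groups = 8L) {
  pad <- (kernel - 1L) %/% 2L
  list(kind = "gnconv", kernel = kernel, pad = pad, groups = groups,
       params = list(W = he_init(kernel * kernel * in_ch, out_ch,
                                 kernel * kernel * in_ch),
                     b = numeric(out_ch), gamma = rep(1, out_ch),
                     beta = numeric(out_ch)))
}

conv1x1_unit <- function(in_ch, out_ch, act = "relu") {
  list(kind = "conv1x1", act = act,
       params = list(W = he_init(in_ch, out_ch, in_ch),
                     b = numeric(out_ch)))
}

gnconv_forward <- function(u, x) {
  cv <- conv_forward(x, u$params$W, u$params$b, u$kernel, u$kernel, u$pad)
  gn <- gn_forward(cv$y, u$params$gamma, u$params$beta, u$groups)
  rl <- relu_forward(gn$y)
  list(y = rl$y, cache = list(cv = cv, gn = gn, rl = rl))
}

gnconv_backward <- function(u, cache, gy) {
  g <- relu_backward(cache$rl, gy)
  gb <- gn_backward(cache$gn, u$params$gamma, g)
  cb <- conv_backward(cache$cv, u$params$W, gb$gx, u$kernel, u$kernel, u$pad)
  list(gx = cb$gx, grads = list(W = cb$gW, b = cb$gb, gamma = gb$dgamma,
                                beta = gb$dbeta))
}

conv1x1_forward <- function(u, x) {
  cv <- conv_forward(x, u$params$W, u$params$b, 1L, 1L, 0L)
  rl <- if (u$act == "relu") relu_forward(cv$y) else list(y = cv$y)
  list(y = rl$y, cache = list(cv = cv, rl = rl))
}

conv1x1_backward <- function(u, cache, gy) {
  g <- if (u$act == "relu") relu_backward(cache$rl, gy) else gy
  cb <- conv_backward(cache$cv, u$params$W, g, 1L, 1L, 0L)
  list(gx = cb$gx, grads = list(W = cb$gW, b = cb$gb))
}

upsample2_forward <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
    drop = FALSE]
}

upsample2_backward <- function(gy) {
  d <- dim(gy)
  i1 <- seq(1L, d[1], 2L); i2 <- seq(2L, d[1], 2L)
  j1 <- seq(1L, d[2], 2L); j2 <- seq(2L, d[2], 2L)
  gy[i1, j1, , , drop = FALSE] + gy[i1, j2, , , drop = FALSE] +
    gy[i2, j1, , , drop = FALSE] + gy[i2, j2, , , drop = FALSE]
}

cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

split_channels <- function(g, ca) {
  list(a = g[, , seq_len(ca), , drop = FALSE],
       b = g[, , -seq_len(ca), , drop = FALSE])
}

# Interleave/merge the two weight-shared image slices of each pair into a
# single 2*C channel slice per sample.
merge_depth_forward <- function(x) {
  d <- dim(x)
  nb <- d[4] %/% 2L
  out <- array(0, c(d[1], d[2], 2L * d[3], nb))
  out[, , seq_len(d[3]), ] <- x[, , , seq(1L, d[4], 2L), drop = FALSE]
  out[, , d[3] + seq_len(d[3]), ] <- x[, , , seq(2L, d[4], 2L), drop = FALSE]
  out
}

merge_depth_backward <- function(g, cin) {
  d <- dim(g)
  out <- array(0, c(d[1], d[2], cin, 2L * d[4]))
  out[, , , seq(1L, 2L * d[4], 2L)] <- g[, , seq_len(cin), , drop = FALSE]
  out[, , , seq(2L, 2L * d[4], 2L)] <- g[, , cin + seq_len(cin), ,
                                         drop = FALSE]
  out
}

#' Build the pixel-score U-Net
#'
#' Three encoder levels (pooling by 8 in total), a bottleneck, three
#' resize-convolution decoder levels with skip connections, and two final
#' 1x1 convolutions projecting the concatenated channels of the two
#' processed images (`2 * start_filters`) through 20 to 4 channels per
#' pixel: three correction components plus an unnormalized score.
#'
#' @param start_filters channels of the first level (default 32; levels
#'   double per pooling).
#' @param seed initialization seed.
#' @return a model of class `sem_unet`.
#' @export
build_pixel_score_model <- function(start_filters = 32L, seed = 1) {
  f <- as.integer(start_filters)
  stopifnot(f %% 8L == 0L)
  with_seed(seed, {
    units <- list(
      e1a = gnconv_unit(1L, f), e1b = gnconv_unit(f, f),
      e2a = gnconv_unit(f, 2L * f), e2b = gnconv_unit(2L * f, 2L * f),
      e3a = gnconv_unit(2L * f, 4L * f), e3b = gnconv_unit(4L * f, 4L * f),
      ba = gnconv_unit(4L * f, 8L * f), bb = gnconv_unit(8L * f, 8L * f),
      u3 = gnconv_unit(8L * f, 4L * f),
      d3a = gnconv_unit(8L * f, 4L * f), d3b = gnconv_unit(4L * f, 4L * f),
      u2 = gnconv_unit(4L * f, 2L * f),
      d2a = gnconv_unit(4L * f, 2L * f), d2b = gnconv_unit(2L * f, 2L * f),
      u1 = gnconv_unit(2L * f, f),
      d1a = gnconv_unit(2L * f, f), d1b = gnconv_unit(f, f),
      h1 = conv1x1_unit(2L * f, 20L, act = "relu"),
      h2 = conv1x1_unit(20L, 4L, act = "linear")
    )
    structure(list(kind = "pixelscore", start_filters = f, depth = 2L,
                   layers = units,
                   normalization = "[0,255] -> [-1,1] (v/127.5 - 1)"),
              class = c("sem_unet", "sem_model"))
  })
}

unet_forward <- function(model, x, training = FALSE) {
  if (dim(x)[1] %% 8L != 0L || dim(x)[2] %% 8L != 0L)
    stop("input side must be divisible by 8 (three pooling levels)",
         call. = FALSE)
  u <- model$layers
  cc <- list()
  r <- gnconv_forward(u$e1a, x); cc$e1a <- r$cache
  r <- gnconv_forward(u$e1b, r$y); cc$e1b <- r$cache; e1 <- r$y
  p1 <- pool_forward(e1, 2L, 2L); cc$p1 <- p1
  r <- gnconv_forward(u$e2a, p1$y); cc$e2a <- r$cache
  r <- gnconv_forward(u$e2b, r$y); cc$e2b <- r$cache; e2 <- r$y
  p2 <- pool_forward(e2, 2L, 2L); cc$p2 <- p2
  r <- gnconv_forward(u$e3a, p2$y); cc$e3a <- r$cache
  r <- gnconv_forward(u$e3b, r$y); cc$e3b <- r$cache; e3 <- r$y
  p3 <- pool_forward(e3, 2L, 2L); cc$p3 <- p3
  r <- gnconv_forward(u$ba, p3$y); cc$ba <- r$cache
  r <- gnconv_forward(u$bb, r$y); cc$bb <- r$cache; bt <- r$y

  r <- gnconv_forward(u$u3, upsample2_forward(bt)); cc$u3 <- r$cache
  d3in <- cat_channels(r$y, e3)
  r <- gnconv_forward(u$d3a, d3in); cc$d3a <- r$cache
  r <- gnconv_forward(u$d3b, r$y); cc$d3b <- r$cache
  r2 <- gnconv_forward(u$u2, upsample2_forward(r$y)); cc$u2 <- r2$cache
  d2in <- cat_channels(r2$y, e2)
  r <- gnconv_forward(u$d2a, d2in); cc$d2a <- r$cache
  r <- gnconv_forward(u$d2b, r$y); cc$d2b <- r$cache
  r2 <- gnconv_forward(u$u1, upsample2_forward(r$y)); cc$u1 <- r2$cache
  d1in <- cat_channels(r2$y, e1)
  r <- gnconv_forward(u$d1a, d1in); cc$d1a <- r$cache
  r <- gnconv_forward(u$d1b, r$y); cc$d1b <- r$cache

  merged <- merge_depth_forward(r$y)
  r <- conv1x1_forward(u$h1, merged); cc$h1 <- r$cache
  r <- conv1x1_forward(u$h2, r$y); cc$h2 <- r$cache
  list(out = r$y, caches = cc)
}

unet_backward <- function(model, caches, gout) {
  u <- model$layers
  f <- model$start_filters
  gr <- list()
  b <- conv1x1_backward(u$h2, caches$h2, gout); gr$h2 <- b$grads
  b <- conv1x1_backward(u$h1, caches$h1, b$gx); gr$h1 <- b$grads
  g <- merge_depth_backward(b$gx, f)
  b <- gnconv_backward(u$d1b, caches$d1b, g); gr$d1b <- b$grads
  b <- gnconv_backward(u$d1a, caches$d1a, b$gx); gr$d1a <- b$grads
  sp <- split_channels(b$gx, f)
  ge1_skip <- sp$b
  b <- gnconv_backward(u$u1, caches$u1, sp$a); gr$u1 <- b$grads
  g <- upsample2_backward(b$gx)
  b <- gnconv_backward(u$d2b, caches$d2b, g); gr$d2b <- b$grads
  b <- gnconv_backward(u$d2a, caches$d2a, b$gx); gr$d2a <- b$grads
  sp <- split_channels(b$gx, 2L * f)
  ge2_skip <- sp$b
  b <- gnconv_backward(u$u2, caches$u2, sp$a); gr$u2 <- b$grads
  g <- upsample2_backward(b$gx)
  b <- gnconv_backward(u$d3b, caches$d3b, g); gr$d3b <- b$grads
  b <- gnconv_backward(u$d3a, caches$d3a, b$gx); gr$d3a <- b$grads
  sp <- split_channels(b$gx, 4L * f)
  ge3_skip <- sp$b
  b <- gnconv_backward(u$u3, caches$u3, sp$a); gr$u3 <- b$grads
  g <- upsample2_backward(b$gx)
  b <- gnconv_backward(u$bb, caches$bb, g); gr$bb <- b$grads
  b <- gnconv_backward(u$ba, caches$ba, b$gx); gr$ba <- b$grads
  g <- pool_backward(caches$p3, b$gx) + ge3_skip
  b <- gnconv_backward(u$e3b, caches$e3b, g); gr$e3b <- b$grads
  b <- gnconv_backward(u$e3a, caches$e3a, b$gx); gr$e3a <- b$grads
  g <- pool_backward(caches$p2, b$gx) + ge2_skip
  b <- gnconv_backward(u$e2b, caches$e2b, g); gr$e2b <- b$grads
  b <- gnconv_backward(u$e2a, caches$e2a, b$gx); gr$e2a <- b$grads
  g <- pool_backward(caches$p1, b$gx) + ge1_skip
  b <- gnconv_backward(u$e1b, caches$e1b, g); gr$e1b <- b$grads
  b <- gnconv_backward(u$e1a, caches$e1a, b$gx); gr$e1a <- b$grads
  gr
}

# Softmax-weighted spatial average of a per-pixel correction field.
pixel_score_reduce <- function(map) {
  d <- dim(map)
  s <- as.vector(map[, , 4L])
  w <- exp(s - max(s))
  w <- w / sum(w)
  est <- vapply(1:3, function(c) sum(as.vector(map[, , c]) * w), 0)
  focus_state(est[1], est[2], est[3])
}

#' Predict per-pixel correction and score maps for patch pairs
#'
#' Each patch pair yields a field of three correction components and one
#' unnormalized score per pixel; the dense prediction is reduced by a
#' softmax-weighted spatial average, and multiple dense predictions are
#' combined by their mean.
#'
#' @param model a `sem_unet` from [build_pixel_score_model()].
#' @param patches list of patch pairs (raw gray levels).
#' @return list with `estimates` (n x 3 matrix), `maps` (list of
#'   `H x W x 4` arrays).
#' @export
predict_dense <- function(model, patches) {
  x <- patches_to_tensor(patches, 2L)
  out <- unet_forward(model, x)$out
  n <- dim(out)[4]
  maps <- lapply(seq_len(n), function(i) out[, , , i])
  est <- do.call(rbind, lapply(maps, function(m)
    as.numeric(pixel_score_reduce(m))))
  colnames(est) <- c("wd", "stig_x", "stig_y")
  list(estimates = est, maps = maps)
}

unet_adamw_init <- function(model) {
  lapply(model$layers, function(u)
    lapply(u$params, function(p) list(m = p * 0, v = p * 0)))
}

unet_adamw_step <- function(model, grads, state, lr, t, weight_decay = 0.01,
                            beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  b1t <- 1 - beta1^t; b2t <- 1 - beta2^t
  for (nm in names(grads)) {
    for (pn in names(grads[[nm]])) {
      g <- grads[[nm]][[pn]]
      st <- state[[nm]][[pn]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      p <- model$layers[[nm]]$params[[pn]]
      upd <- (st$m / b1t) / (sqrt(st$v / b2t) + eps)
      if (pn == "W") upd <- upd + weight_decay * p
      model$layers[[nm]]$params[[pn]] <- p - lr * upd
      state[[nm]][[pn]] <- st
    }
  }
  list(model = model, state = state)
}
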