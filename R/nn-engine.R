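# Minimal CNN engine: tensors are arrays with dim (H, W, C, N) where N runs
# over batch slices (for weight sharing across the two images of a pair,
# the two images are simply adjacent slices processed by the same weights).
# Convolutions are im2col + BLAS matrix products; backward passes are the
# exact adjoints. Everything is deterministic given the R RNG state.

# Convolution in matrix form: the product's rows are ordered (i, j, n)
# fastest-to-slowest and its columns are output channels. Batch norm and
# ReLU of a conv block run directly on this matrix (a column is a channel),
# so each block needs only one aperm per direction, when reshaping to the
# spatial array for pooling.
conv_forward_mat <- function(x, W, b, kh, kw, pad = 0L) {
  d <- dim(x)
  M <- im2col_cpp(x, kh, kw, pad)
  Y <- M %*% W
  if (any(b != 0)) Y <- Y + rep(b, each = nrow(Y))
  list(y = Y, M = M, xdim = d,
       oh = d[1] - kh + 1L + 2L * pad, ow = d[2] - kw + 1L + 2L * pad)
}

conv_backward_mat <- function(cache, W, gy, kh, kw, pad = 0L) {
  gW <- crossprod(cache$M, gy)
  gb <- colSums(gy)
  gM <- tcrossprod(gy, W)
  gx <- col2im_cpp(gM, cache$xdim, kh, kw, pad)
  list(gx = gx, gW = gW, gb = gb)
}

mat_to_array <- function(Y, oh, ow, n) {
  cout <- ncol(Y)
  dim(Y) <- c(oh * ow, n, cout)
  Y <- aperm(Y, c(1, 3, 2))
  dim(Y) <- c(oh, ow, cout, n)
  Y
}

array_to_mat <- function(g) {
  d <- dim(g)
  g <- aperm(g, c(1, 2, 4, 3))
  dim(g) <- c(d[1] * d[2] * d[4], d[3])
  g
}

conv_forward <- function(x, W, b, kh, kw, pad = 0L) {
  cv <- conv_forward_mat(x, W, b, kh, kw, pad)
  cv$y <- mat_to_array(cv$y, cv$oh, cv$ow, cv$xdim[4])
  cv
}

conv_backward <- function(cache, W, gy, kh, kw, pad = 0L) {
  conv_backward_mat(cache, W, array_to_mat(gy), kh, kw, pad)
}

# Batch normalization per channel (= per column of the conv matrix);
# running statistics are updated with momentum 0.1 during training and
# used verbatim at inference.
bn_forward_mat <- function(xp, gamma, beta, rm, rv, training,
                           momentum = 0.1, eps = 1e-5) {
  if (training) {
    r <- bn_fwd_cpp(xp, gamma, beta, eps)
    list(y = r$y, xhat = r$xhat, invstd = r$invstd,
         rm = (1 - momentum) * rm + momentum * r$mu,
         rv = (1 - momentum) * rv + momentum * r$var)
  } else {
    list(y = bn_eval_cpp(xp, rm, rv, gamma, beta, eps), xhat = NULL,
         invstd = NULL, rm = rm, rv = rv)
  }
}

bn_backward_mat <- function(cache, gamma, gp) {
  r <- bn_bwd_cpp(gp, cache$xhat, cache$invstd, gamma)
  list(gx = r$gx, dgamma = r$dgamma, dbeta = r$dbeta)
}

# Group normalization: statistics per (group, sample) across space and the
# group's channels; channelwise affine.
gn_forward <- function(x, gamma, beta, groups, eps = 1e-5) {
  d <- dim(x)
  cg <- d[3] %/% groups
  m <- d[1] * d[2] * cg
  xg <- x
  dim(xg) <- c(m, groups * d[4])
  mu <- colMeans(xg)
  xc <- sweep(xg, 2, mu)
  v <- colMeans(xc * xc)
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, invstd, `*`)
  dim(xhat) <- c(d[1] * d[2], d[3], d[4])
  y <- sweep(xhat, 2, gamma, `*`)
  y <- sweep(y, 2, beta, `+`)
  dim(y) <- d
  dim(xhat) <- c(m, groups * d[4])
  list(y = y, xhat = xhat, invstd = invstd, d = d, groups = groups)
}

gn_backward <- function(cache, gamma, gy) {
  d <- cache$d
  groups <- cache$groups
  cg <- d[3] %/% groups
  m <- d[1] * d[2] * cg
  gp <- gy
  dim(gp) <- c(d[1] * d[2], d[3], d[4])
  xh <- cache$xhat
  dim(xh) <- c(d[1] * d[2], d[3], d[4])
  dgamma <- rowSums(colSums(gp * xh))
  dbeta <- rowSums(colSums(gp))
  dxhat <- sweep(gp, 2, gamma, `*`)
  dim(dxhat) <- c(m, groups * d[4])
  dim(xh) <- c(m, groups * d[4])
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xh)
  gx <- sweep(dxhat * m - rep(s1, each = m) - xh * rep(s2, each = m),
              2, cache$invstd / m, `*`)
  dim(gx) <- d
  list(gx = gx, dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(x) {
  mask <- x > 0
  list(y = x * mask, mask = mask)
}
relu_backward <- function(cache, gy) gy * cache$mask

dropout_forward <- function(x, p, training) {
  if (!training || p <= 0) return(list(y = x, mask = NULL))
  mask <- array((stats::runif(length(x)) >= p) / (1 - p), dim = dim(x))
  list(y = x * mask, mask = mask)
}
dropout_backward <- function(cache, gy) {
  if (is.null(cache$mask)) gy else gy * cache$mask
}

pool_forward <- function(x, ph, pw) {
  if (ph == 1L && pw == 1L) return(list(y = x, idx = NULL, xdim = dim(x)))
  r <- maxpool_fwd_cpp(x, ph, pw)
  list(y = r$out, idx = r$idx, xdim = dim(x))
}
pool_backward <- function(cache, gy) {
  if (is.null(cache$idx)) return(gy)
  maxpool_bwd_cpp(gy, cache$idx, cache$xdim)
}

fc_forward <- function(x, W, b) {
  y <- x %*% W
  y <- y + rep(b, each = nrow(y))
  list(y = y, x = x)
}
fc_backward <- function(cache, W, gy) {
  list(gx = tcrossprod(gy, W), gW = crossprod(cache$x, gy), gb = colSums(gy))
}

# --- layer constructors (parameters drawn from the current RNG state) -----

he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

new_conv_block <- function(in_ch, out_ch, kernel, pool, p_drop = 0.1,
                           batchnorm = TRUE, act = "relu", pad = 0L) {
  list(type = "conv_block", kh = kernel, kw = kernel, pad = as.integer(pad),
       pool = as.integer(pool), p_drop = p_drop, batchnorm = batchnorm,
       act = act, in_ch = in_ch, out_ch = out_ch,
       params = list(W = he_init(kernel * kernel * in_ch, out_ch,
                                 kernel * kernel * in_ch),
                     b = numeric(out_ch),
                     gamma = if (batchnorm) rep(1, out_ch),
                     beta = if (batchnorm) numeric(out_ch)),
       rm = if (batchnorm) numeric(out_ch),
       rv = if (batchnorm) rep(1, out_ch))
}

new_fc_layer <- function(n_in, n_out, act = "relu") {
  list(type = "fc", act = act, n_in = n_in, n_out = n_out,
       params = list(W = he_init(n_in, n_out, n_in), b = numeric(n_out)))
}

new_flatten_layer <- function(depth) list(type = "flatten",
                                          depth = as.integer(depth))

layer_forward <- function(layer, x, training) {
  switch(layer$type,
    conv_block = {
      cv <- conv_forward_mat(x, layer$params$W, layer$params$b, layer$kh,
                             layer$kw, layer$pad)
      y <- cv$y
      bn <- NULL
      if (layer$batchnorm) {
        bn <- bn_forward_mat(y, layer$params$gamma, layer$params$beta,
                             layer$rm, layer$rv, training)
        y <- bn$y
      }
      rl <- if (layer$act == "relu") relu_forward(y) else list(y = y)
      y <- mat_to_array(rl$y, cv$oh, cv$ow, cv$xdim[4])
      pl <- pool_forward(y, layer$pool, layer$pool)
      y <- pl$y
      dr <- dropout_forward(y, layer$p_drop, training)
      list(y = dr$y,
           cache = list(cv = cv, bn = bn, rl = rl, pl = pl, dr = dr),
           state = if (layer$batchnorm && training)
             list(rm = bn$rm, rv = bn$rv))
    },
    flatten = {
      d <- dim(x)
      nb <- d[4] %/% layer$depth
      dim(x) <- c(d[1] * d[2] * d[3] * layer$depth, nb)
      list(y = t(x), cache = list(d = d), state = NULL)
    },
    fc = {
      fc <- fc_forward(x, layer$params$W, layer$params$b)
      rl <- if (layer$act == "relu") relu_forward(fc$y) else list(y = fc$y)
      list(y = rl$y, cache = list(fc = fc, rl = rl), state = NULL)
    },
    stop("unknown layer type"))
}

layer_backward <- function(layer, cache, gy) {
  switch(layer$type,
    conv_block = {
      g <- dropout_backward(cache$dr, gy)
      g <- pool_backward(cache$pl, g)
      g <- array_to_mat(g)
      if (layer$act == "relu") g <- relu_backward(cache$rl, g)
      grads <- list()
      if (layer$batchnorm) {
        bb <- bn_backward_mat(cache$bn, layer$params$gamma, g)
        g <- bb$gx
        grads$gamma <- bb$dgamma
        grads$beta <- bb$dbeta
      }
      cb <- conv_backward_mat(cache$cv, layer$params$W, g, layer$kh,
                              layer$kw, layer$pad)
      grads$W <- cb$gW
      grads$b <- cb$gb
      list(gx = cb$gx, grads = grads)
    },
    flatten = {
      d <- cache$d
      gx <- t(gy)
      dim(gx) <- d
      list(gx = gx, grads = NULL)
    },
    fc = {
      g <- if (layer$act == "relu") relu_backward(cache$rl, gy) else gy
      fb <- fc_backward(cache$fc, layer$params$W, g)
      list(gx = fb$gx, grads = list(W = fb$gW, b = fb$gb))
    })
}

# Forward pass through a stacked model. Returns the output plus per-layer
# caches (for the backward pass) and the model with refreshed batch-norm
# running statistics when training.
model_forward <- function(model, x, training = FALSE) {
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    r <- layer_forward(model$layers[[i]], x, training)
    x <- r$y
    caches[[i]] <- r$cache
    if (!is.null(r$state)) {
      model$layers[[i]]$rm <- r$state$rm
      model$layers[[i]]$rv <- r$state$rv
    }
  }
  sc <- model$output_scale
  if (!is.null(sc) && sc != 1) x <- x * sc
  list(out = x, caches = caches, model = model)
}

model_backward <- function(model, caches, gout) {
  grads <- vector("list", length(model$layers))
  sc <- model$output_scale
  g <- if (!is.null(sc) && sc != 1) gout * sc else gout
  for (i in rev(seq_along(model$layers))) {
    r <- layer_backward(model$layers[[i]], caches[[i]], g)
    g <- r$gx
    grads[i] <- list(r$grads)
  }
  grads
}

# --- AdamW ----------------------------------------------------------------

adamw_init <- function(model) {
  lapply(model$layers, function(l) {
    if (is.null(l$params)) return(NULL)
    lapply(l$params, function(p) if (is.null(p)) NULL else
      list(m = p * 0, v = p * 0))
  })
}

# Decoupled weight decay applied to weight matrices only (biases and
# normalization affines are not decayed).
adamw_step <- function(model, grads, state, lr, t, weight_decay = 0.01,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       trainable = NULL) {
  b1t <- 1 - beta1^t
  b2t <- 1 - beta2^t
  for (i in seq_along(model$layers)) {
    gi <- grads[[i]]
    if (is.null(gi)) next
    if (!is.null(trainable) && !trainable[i]) next
    for (nm in names(gi)) {
      g <- gi[[nm]]
      if (is.null(g)) next
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      p <- model$layers[[i]]$params[[nm]]
      upd <- (st$m / b1t) / (sqrt(st$v / b2t) + eps)
      if (nm == "W") upd <- upd + weight_decay * p
      model$layers[[i]]$params[[nm]] <- p - lr * upd
      state[[i]][[nm]] <- st
    }
  }
  list(model = model, state = state)
}
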