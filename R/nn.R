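# Minimal CNN building blocks on H x W x C x N arrays, backed by the
# compiled im2col kernels.  Parameters live in flat named lists; every
# forward primitive returns what its backward pass needs.

xavier_init <- function(kh, kw, cin, cout) {
  fan_in <- kh * kw * cin
  fan_out <- kh * kw * cout
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(kh * kw * cin * cout, -lim, lim), c(kh, kw, cin, cout))
}

# Bilinear-interpolation kernel for a transpose conv with upsampling
# factor f (kernel size 2f, stride f, pad f/2); channel-diagonal, no bias.
bilinear_kernel <- function(factor, channels) {
  k <- 2L * factor
  ctr <- (k - 1) / 2
  w1 <- 1 - abs(seq_len(k) - 1 - ctr) / factor
  ker <- outer(w1, w1)
  w <- array(0, c(k, k, channels, channels))
  for (c in seq_len(channels)) w[, , c, c] <- ker
  w
}

conv_f <- function(x, w, b, stride = 1L, pad = (dim(w)[1] - 1L) %/% 2L) {
  cpp_conv_fw(x, w, b, as.integer(stride), as.integer(pad))
}
conv_b <- function(x, w, dy, stride = 1L, pad = (dim(w)[1] - 1L) %/% 2L) {
  cpp_conv_bw(x, w, dy, as.integer(stride), as.integer(pad))
}
tconv_f <- function(x, w, factor) {
  cpp_tconv_fw(x, w, as.integer(factor), as.integer(factor / 2))
}
tconv_b <- function(x, w, dy, factor) {
  cpp_tconv_bw(x, w, dy, as.integer(factor), as.integer(factor / 2))
}
pool_f <- function(x, k = 2L) cpp_maxpool_fw(x, as.integer(k))
pool_b <- function(idx, dy, xdim) cpp_maxpool_bw(idx, dy, as.integer(xdim))

relu_f <- function(x) pmax(x, 0)
relu_b <- function(y, dy) dy * (y > 0)

# Batch normalization over (H, W, N) per channel.  `state` carries running
# statistics for inference; training uses batch statistics.
bn_f <- function(x, gamma, beta, state, training, eps = 1e-5,
                 momentum = 0.1) {
  d <- dim(x)
  xm <- aperm(x, c(1, 2, 4, 3))
  dim(xm) <- c(d[1] * d[2] * d[4], d[3])
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    mu <- state$mean
    v <- state$var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, inv, `*`)
  y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  dim(y) <- c(d[1], d[2], d[4], d[3])
  list(y = aperm(y, c(1, 2, 4, 3)), xhat = xhat, inv = inv, state = state)
}

bn_b <- function(cache, gamma, dy) {
  d <- dim(dy)
  dym <- aperm(dy, c(1, 2, 4, 3))
  dim(dym) <- c(d[1] * d[2] * d[4], d[3])
  xhat <- cache$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  m <- nrow(dym)
  dxhat <- sweep(dym, 2, gamma, `*`)
  t1 <- sweep(dxhat, 2, colMeans(dxhat))
  t2 <- sweep(xhat, 2, colMeans(dxhat * xhat), `*`)
  dx <- sweep(t1 - t2, 2, cache$inv, `*`)
  dim(dx) <- c(d[1], d[2], d[4], d[3])
  list(dx = aperm(dx, c(1, 2, 4, 3)), dgamma = dgamma, dbeta = dbeta)
}

# Global average pooling: H x W x C x N -> C x N.
gap_f <- function(x) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1] * d[2], d[3] * d[4])
  m <- colMeans(xm)
  matrix(m, d[3], d[4])
}
gap_b <- function(dy, xdim) {
  out <- array(0, xdim)
  scale <- 1 / (xdim[1] * xdim[2])
  for (n in seq_len(xdim[4]))
    for (c in seq_len(xdim[3]))
      out[, , c, n] <- dy[c, n] * scale
  out
}

fc_f <- function(v, w, b) w %*% v + b          # v: in x N
fc_b <- function(v, w, dy) list(dx = t(w) %*% dy,
                                dw = dy %*% t(v),
                                db = rowSums(dy))

# Column-wise softmax with the max trick.
softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), `/`)
}

# Per-pixel softmax over the channel axis of an H x W x 2 x N array.
softmax_pixels <- function(z) {
  m <- pmax(z[, , 1, , drop = FALSE], z[, , 2, , drop = FALSE])
  e1 <- exp(z[, , 1, , drop = FALSE] - m)
  e2 <- exp(z[, , 2, , drop = FALSE] - m)
  s <- e1 + e2
  z[, , 1, ] <- e1 / s
  z[, , 2, ] <- e2 / s
  z
}

# SGD with momentum over flat parameter/gradient lists.
sgd_step <- function(params, grads, vel, lr, momentum = 0.9) {
  for (nm in names(grads)) {
    if (is.null(vel[[nm]])) vel[[nm]] <- grads[[nm]] * 0
    vel[[nm]] <- momentum * vel[[nm]] - lr * grads[[nm]]
    params[[nm]] <- params[[nm]] + vel[[nm]]
  }
  list(params = params, vel = vel)
}

grad_accum <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (nm in names(g)) {
    acc[[nm]] <- if (is.null(acc[[nm]])) g[[nm]] else acc[[nm]] + g[[nm]]
  }
  acc
}

#' Piecewise-constant learning-rate schedule
#'
#' The rate starts at `lr_start` and is divided by `decay_factor` after
#' every `decay_every` units (epochs or iterations, as the caller counts).
#'
#' @param step 0-based epoch or iteration index (may be a vector).
#' @param lr_start initial learning rate.
#' @param decay_every decay period, in the same units as `step`.
#' @param decay_factor division factor (default 10).
#' @return learning rate(s) at `step`.
#' @export
lr_at <- function(step, lr_start, decay_every, decay_factor = 10) {
  lr_start / decay_factor^(floor(step / decay_every))
}
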