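# RGB <-> HSL conversion, vectorized over H x W x 3 arrays with channels
# in [0, 1].  Hue in degrees [0, 360), saturation and lightness in [0, 1].

rgb_to_hsl <- function(rgb) {
  r <- rgb[, , 1]; g <- rgb[, , 2]; b <- rgb[, , 3]
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  l <- (mx + mn) / 2
  d <- mx - mn
  s <- ifelse(d == 0, 0, d / (1 - abs(2 * l - 1)))
  h <- matrix(0, nrow(r), ncol(r))
  idx <- d > 0 & mx == r
  h[idx] <- 60 * (((g - b)[idx] / d[idx]) %% 6)
  idx <- d > 0 & mx == g & mx != r
  h[idx] <- 60 * ((b - r)[idx] / d[idx] + 2)
  idx <- d > 0 & mx == b & mx != r & mx != g
  h[idx] <- 60 * ((r - g)[idx] / d[idx] + 4)
  out <- array(0, dim(rgb))
  out[, , 1] <- h; out[, , 2] <- s; out[, , 3] <- l
  out
}

hsl_to_rgb <- function(hsl) {
  h <- hsl[, , 1]; s <- hsl[, , 2]; l <- hsl[, , 3]
  ch <- (1 - abs(2 * l - 1)) * s
  hp <- (h %% 360) / 60
  x <- ch * (1 - abs(hp %% 2 - 1))
  m <- l - ch / 2
  r1 <- g1 <- b1 <- matrix(0, nrow(h), ncol(h))
  seg <- floor(hp)
  set <- function(cond, rv, gv, bv) {
    r1[cond] <<- rv[cond]; g1[cond] <<- gv[cond]; b1[cond] <<- bv[cond]
  }
  zero <- matrix(0, nrow(h), ncol(h))
  set(seg == 0, ch, x, zero)
  set(seg == 1, x, ch, zero)
  set(seg == 2, zero, ch, x)
  set(seg == 3, zero, x, ch)
  set(seg == 4, x, zero, ch)
  set(seg >= 5, ch, zero, x)
  out <- array(0, dim(hsl))
  out[, , 1] <- r1 + m; out[, , 2] <- g1 + m; out[, , 3] <- b1 + m
  out
}
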