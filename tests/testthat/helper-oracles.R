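# Brute-force reference implementations used as independent oracles.

# Naive deformable convolution: explicit loops over output positions, taps,
# channels and the full interpolation sum over every input position.
brute_deformable_conv <- function(X, layer) {
  W <- layer$W
  out_ch <- dim(W)[1]; nin <- dim(W)[2]; K <- dim(W)[3]
  L <- ncol(X)
  J <- dim(layer$OW)[3]; half <- (J - 1) / 2
  delta <- matrix(0, K, L)
  for (k in 1:K) for (i in 1:L) {
    s <- 0
    for (c in 1:nin) for (j in 1:J) {
      ii <- i + j - 1 - half
      if (ii >= 1 && ii <= L) s <- s + layer$OW[k, c, j] * X[c, ii]
    }
    delta[k, i] <- s
  }
  rel <- (1:K) - (K + 1) / 2
  Y <- matrix(0, out_ch, L)
  for (o in 1:out_ch) for (i in 1:L) {
    acc <- 0
    for (c in 1:nin) for (k in 1:K) {
      it <- i + rel[k] + delta[k, i]
      v <- 0
      for (vv in 1:L) {
        g <- max(0, 1 - abs(vv - it))
        if (g > 0) v <- v + g * X[c, vv]
      }
      acc <- acc + W[o, c, k] * v
    }
    Y[o, i] <- acc
  }
  Y
}

brute_deformable_pool <- function(X, layer) {
  win <- layer$window
  nin <- nrow(X); L <- ncol(X); m <- L %/% win
  J <- dim(layer$OW)[3]; half <- (J - 1) / 2
  delta <- matrix(0, win, L)
  for (k in 1:win) for (i in 1:L) {
    s <- 0
    for (c in 1:nin) for (j in 1:J) {
      ii <- i + j - 1 - half
      if (ii >= 1 && ii <= L) s <- s + layer$OW[k, c, j] * X[c, ii]
    }
    delta[k, i] <- s
  }
  Y <- matrix(0, nin, m)
  for (c in 1:nin) for (jj in 1:m) {
    acc <- 0
    for (w in 1:win) {
      b <- (jj - 1) * win + w
      it <- b + delta[w, b]
      v <- 0
      for (vv in 1:L) {
        g <- max(0, 1 - abs(vv - it))
        if (g > 0) v <- v + g * X[c, vv]
      }
      acc <- acc + v
    }
    Y[c, jj] <- acc / win
  }
  Y
}

# Textbook convolve-decimate split (zero extension, even-phase decimation).
brute_filter_split <- function(x, lp, hp) {
  n <- length(x); m <- length(lp)
  full <- function(f) {
    out <- numeric(n + m - 1)
    for (j in seq_along(out)) {
      acc <- 0
      for (t in seq_len(n)) {
        k <- j - t + 1
        if (k >= 1 && k <= m) acc <- acc + x[t] * f[k]
      }
      out[j] <- acc
    }
    out
  }
  keep <- seq(1, n + m - 1, by = 2)
  list(low = full(lp)[keep], high = full(hp)[keep])
}

random_layer <- function(nin, out_ch, K, offset_sd = 0.3) {
  list(W = array(stats::rnorm(out_ch * nin * K, sd = 0.5), c(out_ch, nin, K)),
       OW = array(stats::rnorm(K * nin * 3, sd = offset_sd), c(K, nin, 3)))
}

random_pool_layer <- function(nin, win = 2L, offset_sd = 0.3) {
  list(window = win,
       OW = array(stats::rnorm(win * nin * 3, sd = offset_sd), c(win, nin, 3)))
}
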