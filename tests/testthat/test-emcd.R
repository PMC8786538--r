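test_that("extrema detection finds strict alternating extrema with plateau midpoints", {
  expect_equal(nrow(find_extrema(1:50)$maxima), 0)     # monotone ramp
  expect_equal(nrow(find_extrema(1:50)$minima), 0)
  t <- seq(0, 5 - 1e-9, length.out = 500)
  s <- sin(2 * pi * t)
  ex <- find_extrema(s)
  expect_equal(nrow(ex$maxima), 5)
  expect_equal(nrow(ex$minima), 5)
  # plateau midpoint convention
  xp <- c(0, 1, 2, 2, 2, 1, 0)
  exp_ <- find_extrema(xp)
  expect_equal(exp_$maxima$index, 4)
  # alternation on random walks, against a brute-force neighbour comparison
  set.seed(1)
  for (rep in 1:5) {
    w <- cumsum(rnorm(300))
    ex <- find_extrema(w)
    merged <- rbind(data.frame(i = ex$maxima$index, kind = 1),
                    data.frame(i = ex$minima$index, kind = -1))
    merged <- merged[order(merged$i), ]
    expect_true(all(diff(merged$kind) != 0))   # maxima and minima alternate
    # brute force: strict local extrema away from endpoints
    brute_max <- which(w > c(Inf, w[-300]) & w > c(w[-1], Inf))
    expect_setequal(ex$maxima$index, brute_max)
  }
})

test_that("spline envelopes interpolate the extrema and track a pure tone", {
  # two equal-valued maxima: constant envelope at that value
  x <- c(0, 2, 0, 2, 0)
  ex <- find_extrema(x)
  expect_true(all(abs(envelope(ex, 5, "superior") - 2) < 1e-12))
  # the superior envelope meets the signal at every maximum
  set.seed(2)
  y <- cumsum(rnorm(200))
  exy <- find_extrema(y)
  env <- envelope(exy, 200, "superior")
  expect_lt(max(abs(env[exy$maxima$index] - exy$maxima$value)), 1e-9)
  # dense sine: superior envelope close to +1 away from the ends
  t <- seq(0, 20 - 1e-9, length.out = 2000)
  s <- sin(2 * pi * t)
  es <- envelope(find_extrema(s), 2000, "superior")
  mid <- 200:1800
  expect_lt(max(abs(es[mid] - 1)), 0.05)
  expect_error(envelope(find_extrema(1:10), 10, "superior"),
               class = "ocuclean_needs_extrema")
})

test_that("mean curve averages the envelopes with affine equivariance", {
  t <- seq(0, 20 - 1e-9, length.out = 2000)
  s <- sin(2 * pi * t)
  mc <- mean_curve(s)
  expect_lt(max(abs(mc[200:1800])), 0.05)
  # adding a constant shifts the mean curve by exactly that constant
  mc_c <- mean_curve(s + 3.7)
  expect_lt(max(abs(mc_c - mc - 3.7)), 1e-9)
  # symmetric triangle wave: mean curve close to its midline
  tri <- rep(c(seq(0, 1, length.out = 25), seq(1, 0, length.out = 25)), 10)
  mtri <- mean_curve(tri)
  inner <- 100:(length(tri) - 100)
  expect_lt(max(abs(mtri[inner] - 0.5)), 0.1)
})

test_that("empirical waveform statistics count cycles", {
  t <- seq(0, 5 - 1e-9, length.out = 500)
  s <- sin(2 * pi * t)
  st <- ewf_stats(s)
  expect_equal(st$mode_count, 5)
  expect_equal(st$empirical_period, 100)
  expect_equal(st$empirical_frequency, 0.01)
  expect_equal(st$empirical_period * st$empirical_frequency, 1, tolerance = 1e-10)
  # amplitude scaling leaves the mode count unchanged
  expect_equal(ewf_stats(10 * s)$mode_count, 5)
  # constant signal: degenerate convention
  stc <- ewf_stats(rep(2, 100))
  expect_equal(stc$mode_count, 0)
  expect_true(is.nan(stc$empirical_period))
  expect_true(is.nan(stc$empirical_frequency))
})

test_that("EMCD conserves the signal and separates time scales", {
  set.seed(3)
  for (rep in 1:100) {
    x <- rnorm(120) + cumsum(rnorm(120, sd = 0.3))
    r <- emcd_decompose(x, 5)
    rec <- inverse_emcd(r$modes, r$leftover)
    expect_lt(max(abs(rec - x)) / max(abs(x)), 1e-8)
  }
  # constant input: no extrema, no modes, leftover is the input
  rc <- emcd_decompose(rep(1, 50))
  expect_equal(rc$n_levels, 0)
  expect_identical(rc$leftover, rep(1, 50))
  expect_error(emcd_decompose(rnorm(5)), class = "ocuclean_decomposition_error")
  # fast + slow tone: the first mode holds the fast 8-cycle component
  t <- seq(0, 1 - 1e-9, length.out = 1000)
  x2 <- sin(2 * pi * 8 * t) + 0.5 * sin(2 * pi * 0.5 * t)
  r2 <- emcd_decompose(x2, 5)
  sp <- Mod(stats::fft(r2$modes[[1]]))^2
  cycles <- 0:(length(sp) - 1)
  band <- cycles >= 6 & cycles <= 10
  half <- 1:(length(sp) / 2)
  expect_gt(sum(sp[half][band[half]]) / sum(sp[half]), 0.8)
  # successive leftovers get smoother: counts of significant extrema are
  # nonincreasing (the deep mean curves are flat to machine precision, so the
  # raw count picks up float-level jitter; quantizing removes it)
  set.seed(4)
  x3 <- rnorm(500)
  sig_extrema <- function(v) nrow(find_extrema(round(v / stats::sd(x3), 8))$maxima)
  cur <- x3
  counts <- integer(0)
  r3 <- emcd_decompose(x3, 5)
  for (m in r3$modes) {
    counts <- c(counts, sig_extrema(cur))
    cur <- cur - m
  }
  counts <- c(counts, sig_extrema(cur))
  expect_true(all(diff(counts) <= 0))
})

test_that("inverse EMCD is plain summation with the documented contracts", {
  set.seed(5)
  x <- rnorm(100) + sin(seq_len(100) / 5)
  r <- emcd_decompose(x, 3)
  expect_equal(inverse_emcd(r$modes, r$leftover), x, tolerance = 1e-12)
  expect_identical(inverse_emcd(list(), r$leftover), r$leftover)
  # additivity: summation is linear, with the leftover counted once
  doubled <- inverse_emcd(lapply(r$modes, function(m) 2 * m), r$leftover)
  expect_equal(doubled, 2 * inverse_emcd(r$modes, r$leftover) - r$leftover,
               tolerance = 1e-12)
  expect_error(inverse_emcd(list(rnorm(5)), r$leftover),
               class = "ocuclean_argument_error")
})
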