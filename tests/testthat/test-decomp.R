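test_that("filter split matches the textbook convolve-decimate reference and inverts", {
  f <- ocuclean:::wavelet_filter("db4")
  set.seed(1)
  x <- rnorm(256)
  s <- dwt_filter_split(x, "db4")
  ref <- brute_filter_split(x, f$lo, f$hi)
  expect_lt(max(abs(s$low - ref$low)), 1e-10)
  expect_lt(max(abs(s$high - ref$high)), 1e-10)
  # length convention: ceil((n + filterlen - 1) / 2)
  expect_length(s$low, ceiling((256 + 8 - 1) / 2))
  expect_length(s$high, length(s$low))
  # adjoint reconstruction and energy conservation (orthogonal filter bank)
  rec <- idwt_filter_merge(s$low, s$high, 256, "db4")
  expect_lt(max(abs(rec - x)), 1e-8)
  energy <- sum(s$low^2) + sum(s$high^2)
  expect_lt(abs(energy - sum(x^2)) / sum(x^2), 1e-6)
  # constant input: vanishing moments zero the interior high-band coefficients
  # (boundary taps see the zero extension and are excluded)
  s1 <- dwt_filter_split(rep(1, 128), "db4")
  interior <- s1$high[5:(length(s1$high) - 4)]
  expect_lt(max(abs(interior)), 1e-10)
  expect_error(dwt_filter_split(rnorm(4), "db4"),
               class = "ocuclean_decomposition_error")
})

test_that("five-level cascade yields 20 shrinking subbands and handles edge cases", {
  set.seed(2)
  x <- rnorm(1500)
  sb <- dwt5_decompose(x, "db4")
  expect_s3_class(sb, "subband_set")
  expect_length(sb$levels, 5)
  for (lev in 1:5) {
    bands <- sb$levels[[lev]]
    expect_named(bands, c("LFLF", "LFHF", "HFLF", "HFHF"))
    lens <- lengths(bands)
    expect_true(all(lens == lens[1]))
    if (lev > 1)
      expect_lt(lens[1], length(sb$levels[[lev - 1]]$LFLF))
  }
  # zero signal propagates to 20 zero vectors
  sbz <- dwt5_decompose(numeric(1500))
  expect_true(all(vapply(sbz$levels, function(l) all(unlist(l) == 0), logical(1))))
  # a signal shorter than the filter reports the maximum feasible depth
  err <- tryCatch(dwt5_decompose(rnorm(6), "db4"), error = identity)
  expect_s3_class(err, "ocuclean_decomposition_error")
  expect_match(conditionMessage(err), "levels")
  # a high-frequency tone concentrates energy in the level-1 HF-derived bands
  tone <- sin(2 * pi * 0.45 * seq_len(2048))
  sbt <- dwt5_decompose(tone)
  l1 <- sbt$levels[[1]]
  hf <- sum(l1$HFLF^2) + sum(l1$HFHF^2)
  tot <- sum(unlist(l1)^2)
  expect_gt(hf / tot, 0.9)
})

test_that("Pisarenko analysis recovers tone frequencies", {
  t <- 0:511
  set.seed(3)
  x <- cos(2 * pi * 0.1 * t) + rnorm(512, sd = 1e-3)
  p <- pisarenko_analyze(x, model_order = 3, grid_size = 256)
  expect_true(all(p$pseudospectrum > 0), info = "strictly positive pseudospectrum")
  expect_true(all(is.finite(p$pseudospectrum)))
  expect_lt(abs(p$dominant_freqs[1] - 0.1), 0.002)
  # scale invariance of the eigenvector direction
  p10 <- pisarenko_analyze(10 * x, model_order = 3, grid_size = 256)
  expect_equal(p$dominant_freqs, p10$dominant_freqs)
  # all frequencies reported in [0, 0.5)
  expect_true(all(p$dominant_freqs >= 0 & p$dominant_freqs < 0.5))
  expect_error(pisarenko_analyze(numeric(100), 3, 64),
               class = "ocuclean_analysis_error")
  expect_error(pisarenko_analyze(rnorm(10), model_order = 8),
               class = "ocuclean_argument_error")
})

test_that("two-tone Pisarenko matches the polynomial-rooting oracle within a grid bin", {
  t <- 0:1023
  set.seed(4)
  x <- cos(2 * pi * 0.1 * t) + 0.8 * cos(2 * pi * 0.3 * t) + rnorm(1024, sd = 1e-3)
  p <- pisarenko_analyze(x, model_order = 5, grid_size = 256)
  # oracle: roots of the minimum-eigenvector polynomial (classic identity)
  n <- length(x); M <- 5
  r <- vapply(0:(M - 1), function(k) mean(x[1:(n - k)] * x[(1 + k):n]), numeric(1))
  v <- eigen(stats::toeplitz(r), symmetric = TRUE)$vectors[, M]
  roots <- polyroot(v)
  fr <- Arg(roots) / (2 * pi)
  fr <- sort(unique(round(fr[fr > 1e-6 & fr < 0.5 - 1e-6], 6)))
  bin <- 0.5 / 256
  top2 <- sort(p$dominant_freqs[1:2])
  expect_equal(length(fr), 2)
  expect_lt(abs(top2[1] - fr[1]), bin + 1e-9)
  expect_lt(abs(top2[2] - fr[2]), bin + 1e-9)
  # and the oracle itself sits on the true tones
  expect_lt(abs(fr[1] - 0.1), 0.002)
  expect_lt(abs(fr[2] - 0.3), 0.002)
})

test_that("epoch decomposition carries a Pisarenko result or empty marker per subband", {
  set.seed(5)
  x <- rnorm(1500)
  d <- decompose_epoch(x)
  expect_s3_class(d, "decomposed_signal")
  expect_length(d$pisarenko, 20)
  ok <- vapply(d$pisarenko, function(p)
    is_empty_pisarenko(p) || inherits(p, "pisarenko_result"), logical(1))
  expect_true(all(ok))
  # deep subbands are too short for the order-8 model and get the empty marker
  expect_true(is_empty_pisarenko(d$pisarenko[["L5.LFLF"]]))
  expect_false(is_empty_pisarenko(d$pisarenko[["L1.LFLF"]]))
  # deterministic
  d2 <- decompose_epoch(x)
  expect_identical(d$pisarenko[["L1.HFHF"]]$pseudospectrum,
                   d2$pisarenko[["L1.HFHF"]]$pseudospectrum)
})
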