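test_that("interpolation kernel and fractional sampling follow the closed forms", {
  expect_equal(interp_kernel(3, 3), 1)
  expect_equal(interp_kernel(3, 4.2), 0)
  expect_equal(interp_kernel(0, 0.25), 0.75)
  f <- c(2, 4, 6, 8)
  expect_equal(sample_fractional(f, 3), 6)          # integer position is exact
  expect_equal(sample_fractional(f, 2.5), 5)        # midpoint is the mean
  expect_equal(sample_fractional(f, -3), 0)         # out of range contributes 0
  # random positions match the brute-force sum over all v
  set.seed(1)
  feat <- rnorm(12)
  for (it in runif(20, -2, 15)) {
    brute <- sum(vapply(1:12, function(v) interp_kernel(v, it) * feat[v], numeric(1)))
    expect_equal(sample_fractional(feat, it), brute, tolerance = 1e-12)
  }
})

test_that("deformable convolution equals the brute-force oracle and its reductions", {
  set.seed(2)
  for (case in 1:10) {
    nin <- sample(1:3, 1); out_ch <- sample(1:4, 1)
    K <- sample(c(3, 5), 1); L <- sample(8:20, 1)
    X <- matrix(rnorm(nin * L), nin, L)
    layer <- random_layer(nin, out_ch, K)
    expect_lt(max(abs(deformable_conv_forward(X, layer) -
                        brute_deformable_conv(X, layer))), 1e-6)
  }
  # zero offsets reduce to the standard cross-correlation
  X <- matrix(rnorm(2 * 15), 2, 15)
  layer <- random_layer(2, 3, 3, offset_sd = 0)
  Y <- deformable_conv_forward(X, layer)
  std <- matrix(0, 3, 15)
  for (o in 1:3) for (i in 1:15) {
    acc <- 0
    for (c in 1:2) for (k in 1:3) {
      ii <- i + k - 2
      if (ii >= 1 && ii <= 15) acc <- acc + layer$W[o, c, k] * X[c, ii]
    }
    std[o, i] <- acc
  }
  expect_lt(max(abs(Y - std)), 1e-12)
  # all-zero input gives all-zero output (no bias anywhere)
  expect_true(all(deformable_conv_forward(matrix(0, 2, 15), layer) == 0))
  expect_error(deformable_conv_forward(X, list(W = array(0, c(2, 2, 4)),
                                               OW = array(0, c(4, 2, 3)))),
               class = "ocuclean_argument_error")
})

test_that("deformable pooling equals the brute-force oracle and its reductions", {
  set.seed(3)
  for (case in 1:10) {
    nin <- sample(1:3, 1); L <- sample(c(8, 10, 14), 1)
    X <- matrix(rnorm(nin * L), nin, L)
    layer <- random_pool_layer(nin)
    expect_lt(max(abs(deformable_pool_forward(X, layer) -
                        brute_deformable_pool(X, layer))), 1e-6)
  }
  # zero offsets: ordinary average pooling
  X <- matrix(rnorm(2 * 12), 2, 12)
  lz <- random_pool_layer(2, offset_sd = 0)
  Y <- deformable_pool_forward(X, lz)
  expect_equal(Y, (X[, seq(1, 11, 2)] + X[, seq(2, 12, 2)]) / 2, tolerance = 1e-12)
  # constant input stays constant
  Yc <- deformable_pool_forward(matrix(3, 2, 12), lz)
  expect_true(all(abs(Yc - 3) < 1e-12))
})

test_that("heads implement the documented affine maps and tie rule", {
  # zero weights and bias: sigmoid gives 0.5, tie rule labels negative
  head0 <- list(type = "detector", w = numeric(6), b = 0)
  expect_equal(head_forward(matrix(1, 2, 3), head0), 0.5)
  expect_equal(as.integer(head_forward(matrix(1, 2, 3), head0) > 0.5), 0L)
  # logits match a hand-computed affine map on a 3 x 2 feature map
  F <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2)
  hw <- c(0.1, -0.2, 0.3, 0.4, -0.5, 0.6)
  z <- sum(hw * as.vector(F)) + 0.25
  hd <- list(type = "detector", w = hw, b = 0.25)
  expect_equal(head_forward(F, hd), 1 / (1 + exp(-z)), tolerance = 1e-12)
  # denoiser: position-wise affine across channels
  hden <- list(type = "denoiser", w = c(2, -1, 0.5), b = 1)
  expect_equal(head_forward(F, hden), as.vector(t(F) %*% c(2, -1, 0.5)) + 1)
})

test_that("batched network passes agree with the per-sample reference", {
  set.seed(4)
  spec <- detector_spec(20)
  params <- ocuclean:::dcn_init(spec, seed = 2)
  for (i in seq_along(params$layers))
    params$layers[[i]]$OW[] <- rnorm(length(params$layers[[i]]$OW), sd = 0.3)
  ins <- lapply(1:5, function(i) matrix(rnorm(20), 1))
  y <- c(1, 0, 1, 0, 1)
  fw <- ocuclean:::dcn_forward_b(params, ins, want_cache = TRUE)
  single <- vapply(ins, function(x) ocuclean:::dcn_forward(params, x)$output,
                   numeric(1))
  expect_lt(max(abs(unlist(fw$outputs) - single)), 1e-12)
  dOuts <- lapply(1:5, function(k) fw$outputs[[k]] - y[k])
  gb <- ocuclean:::dcn_backward_b(params, fw, dOuts)
  acc <- NULL
  for (k in 1:5) {
    fws <- ocuclean:::dcn_forward(params, ins[[k]], want_cache = TRUE)
    g <- ocuclean:::dcn_backward(params, fws, fws$output - y[k])
    acc <- if (is.null(acc)) g else ocuclean:::add_grads(acc, g)
  }
  err <- max(abs(acc$head$dw - gb$head$dw))
  for (li in seq_along(params$layers))
    for (nm in intersect(names(gb$layers[[li]]), c("dW", "dOW")))
      err <- max(err, max(abs(acc$layers[[li]][[nm]] - gb$layers[[li]][[nm]])))
  expect_lt(err, 1e-10)
})

test_that("training separates well-separated classes and is seed-deterministic", {
  set.seed(3)
  n <- 200
  y <- rep(c(0, 1), each = n / 2)
  X <- rbind(matrix(rnorm(n / 2 * 2), ncol = 2),
             matrix(rnorm(n / 2 * 2, mean = 6), ncol = 2))
  Xs <- scale(X)
  inputs <- lapply(seq_len(n), function(i) matrix(Xs[i, ], 1))
  spec <- dcn_spec(1L, 2L, list(list(type = "dconv", out_ch = 8L, kernel = 3L)),
                   head = "detector")
  m <- dcn_train(spec, inputs, y, network_config(epochs = 15, learning_rate = 0.3,
                                                 seed = 4))
  acc <- mean(dcn_predict(m, inputs, "label") == y)
  expect_gte(acc, 0.95)
  expect_true(all(is.finite(m$loss_curve)))
  m2 <- dcn_train(spec, inputs, y, network_config(epochs = 15, learning_rate = 0.3,
                                                  seed = 4))
  expect_identical(m$params$head$w, m2$params$head$w)
  expect_identical(m$params$layers[[1]]$W, m2$params$layers[[1]]$W)
})

test_that("denoiser learns the identity task with a decreasing loss", {
  set.seed(1)
  L <- 64
  ins <- lapply(1:80, function(i) rnorm(L))
  m <- dcn_train(denoiser_spec(L), ins, ins,
                 network_config(epochs = 200, learning_rate = 0.5, seed = 7))
  preds <- dcn_predict(m, ins, "signal")
  mae <- mean(vapply(seq_along(ins), function(i) mean(abs(preds[[i]] - ins[[i]])),
                     numeric(1)))
  expect_lte(mae, 0.05)   # 0.05 x unit input scale
  # 5-epoch moving average of the loss decreases overall
  ma <- stats::filter(m$loss_curve, rep(1 / 5, 5), sides = 1)
  ma <- ma[!is.na(ma)]
  expect_lt(ma[length(ma)], ma[1])
  expect_gt(mean(diff(ma) <= 1e-8), 0.8)
})

test_that("hyperparameter tuning stays inside the printed search box", {
  set.seed(5)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  X <- rbind(matrix(rnorm(n / 2 * 2), ncol = 2),
             matrix(rnorm(n / 2 * 2, mean = 6), ncol = 2))
  Xs <- scale(X)
  inputs <- lapply(seq_len(n), function(i) matrix(Xs[i, ], 1))
  spec <- dcn_spec(1L, 2L, list(list(type = "dconv", out_ch = 4L, kernel = 3L)),
                   head = "detector")
  idx <- sample(n)
  tr <- idx[1:40]; va <- idx[41:60]
  tp <- efo_params(matrix(c(10, 20, 0.1, 0.9), 2), pop_size = 3, iterations = 2,
                   seed = 1)
  tuned <- tune_hyperparams(spec, inputs[tr], y[tr], inputs[va], y[va],
                            task = "detect", dsefo_params = tp, seed = 6)
  expect_true(tuned$config$epochs == round(tuned$config$epochs))
  expect_gte(tuned$config$epochs, 10)
  expect_lte(tuned$config$epochs, 20)
  expect_gte(tuned$config$learning_rate, 0.1)
  expect_lte(tuned$config$learning_rate, 0.9)
  # a perfect classifier on the validation split gives fitness exactly 0.5,
  # the lower bound of 1/(accuracy + precision)
  expect_gte(tuned$fitness, 0.5)
  # detection objective at the reported operating point: 1/(0.9440 + 0.701)
  expect_equal(1 / (0.9440 + 0.701), 0.6079, tolerance = 1e-3)
})

test_that("training aborts with a diagnostic on divergent loss", {
  # exploding inputs at a large step make the MAE head race to non-finite values
  set.seed(8)
  ins <- lapply(1:8, function(i) rnorm(16) * 1e200)
  tg <- lapply(1:8, function(i) rnorm(16) * 1e200)
  expect_error(
    dcn_train(denoiser_spec(16), ins, tg,
              network_config(epochs = 20, learning_rate = 0.9, seed = 1)),
    class = "ocuclean_training_error")
})
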