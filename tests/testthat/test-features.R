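make_decomposed <- function(n_epochs, len = 1200, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_epochs), function(e) decompose_epoch(rnorm(len)))
}

test_that("flattening yields 100 deterministic per-subband statistics", {
  dec <- make_decomposed(3)
  X <- flatten_decomposed(dec)
  expect_equal(dim(X), c(3, 100))
  expect_true(all(is.finite(X)))
  expect_identical(colnames(X)[1:5],
                   paste("L1.LFLF", c("mean", "var", "energy", "domfreq", "entropy"),
                         sep = "."))
  X2 <- flatten_decomposed(dec)
  expect_identical(X, X2)
  # zero epoch: all statistics zero, entropy zero by convention
  z <- decompose_epoch(numeric(1200))
  Xz <- flatten_decomposed(list(z))
  expect_true(all(Xz == 0))
  expect_error(flatten_decomposed(list()), class = "ocuclean_argument_error")
})

test_that("PCA matches the SVD oracle and is a complete orthonormal projection", {
  set.seed(10)
  X <- matrix(rnorm(20 * 10), 20, 10)
  r <- pca_fit_transform(X, 10)
  # oracle: singular value decomposition of the centered matrix
  Xc <- scale(X, scale = FALSE)
  sv <- svd(Xc)
  expect_equal(r$model$eigenvalues[1:10], sv$d^2 / 19, tolerance = 1e-8)
  for (j in 1:10) {
    v <- sv$v[, j]
    i <- which.max(abs(v))
    if (v[i] < 0) v <- -v
    expect_lt(max(abs(r$model$eigenvectors[, j] - v)), 1e-8)
  }
  # orthonormal columns
  G <- crossprod(r$model$eigenvectors)
  expect_lt(max(abs(G - diag(10))), 1e-8)
  # projecting then back-projecting with all components reproduces centered data
  back <- r$scores %*% t(r$model$eigenvectors[, 1:10])
  expect_lt(max(abs(back - Xc)), 1e-8)
  # score variance nonincreasing across columns
  vars <- apply(r$scores, 2, stats::var)
  expect_true(all(diff(vars) <= 1e-10))
  expect_error(pca_fit_transform(X, 11), class = "ocuclean_config_error")
})

test_that("PCA eigenvalue ratio recovers a known diagonal covariance", {
  set.seed(11)
  n <- 1e4
  X <- cbind(rnorm(n, sd = 2), rnorm(n, sd = 1))
  r <- pca_fit_transform(X, 2)
  expect_lt(abs(r$model$eigenvalues[1] / r$model$eigenvalues[2] - 4), 0.4)
})

test_that("ICA recovers independent sources up to permutation and sign", {
  set.seed(6)
  n <- 5000
  S <- cbind(stats::runif(n, -1, 1), stats::runif(n, -1, 1))
  A <- matrix(c(1, 0.5, 0.5, 1), 2)
  X <- S %*% t(A)
  r <- ica_fit_transform(X, 2, seed = 3)
  cc <- abs(stats::cor(r$scores, S))
  expect_gt(max(cc[, 1]), 0.95)
  expect_gt(max(cc[, 2]), 0.95)
  expect_false(r$model$non_identifiable)
  # unmixing rows unit-norm
  expect_equal(unname(sqrt(rowSums(r$model$unmixing^2))), c(1, 1), tolerance = 1e-8)
  # seeded determinism
  r2 <- ica_fit_transform(X, 2, seed = 3)
  expect_identical(r$model$unmixing, r2$model$unmixing)
  # Gaussian-only input: still returns, flagged non-identifiable
  G <- matrix(stats::rnorm(2 * n), ncol = 2)
  rg <- suppressWarnings(ica_fit_transform(G, 2, seed = 4))
  expect_true(rg$model$non_identifiable)
})

test_that("ICA permutation/scale-invariant recovery error is small on 3 sources", {
  set.seed(5)
  n <- 5000
  S <- cbind(stats::runif(n, -1, 1), stats::runif(n, -1, 1)^3, sin(seq_len(n) / 7))
  A <- matrix(c(1, .4, .2, .3, 1, .5, .2, .3, 1), 3, 3)
  X <- S %*% t(A)
  r <- ica_fit_transform(X, 3, seed = 2)
  P <- abs(r$model$unmixing %*% A)
  k <- nrow(P)
  amari <- (sum(rowSums(P / apply(P, 1, max)) - 1) +
              sum(colSums(P / matrix(apply(P, 2, max), k, k, byrow = TRUE)) - 1)) /
    (2 * k * (k - 1))
  expect_lt(amari, 0.1)
})

test_that("feature concatenation keeps the PCA block first with exact tags", {
  p <- matrix(1, 4, 5); i <- matrix(2, 4, 3)
  fm <- concat_features(p, i)
  expect_s3_class(fm, "feature_matrix")
  expect_equal(ncol(fm$values), 8)
  expect_identical(fm$method_tags, c(rep("PCA", 5), rep("ICA", 3)))
  expect_equal(unname(fm$component_count), c(5L, 3L))
  # empty ICA block degenerates to the PCA block
  fm2 <- concat_features(p, NULL)
  expect_identical(fm2$values, p)
  expect_true(all(fm2$method_tags == "PCA"))
  expect_error(concat_features(p, matrix(1, 3, 2)),
               class = "ocuclean_argument_error")
})
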