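# Feature extraction: per-subband summary statistics, PCA and ICA feature
# extractors, and their concatenation (PCA block first).

#' Flatten decomposed epochs into an observation matrix
#'
#' Each epoch becomes one row of per-subband summary statistics, in a fixed
#' documented order: subbands level-major (`L1.LFLF`, `L1.LFHF`, `L1.HFLF`,
#' `L1.HFHF`, `L2.LFLF`, ...), and within each subband the five statistics
#' `mean`, `var`, `energy` (sum of squares), `domfreq` (strongest dominant
#' Pisarenko frequency, 0 when none or when the subband analysis is empty)
#' and `entropy` (Shannon entropy of the normalized pseudospectrum, 0 by
#' convention for empty or degenerate subbands). 20 subbands x 5 statistics =
#' 100 variables.
#'
#' @param decomposed list of `decomposed_signal` objects, one per epoch.
#' @return numeric matrix `[n_epochs x 100]` with named columns.
#' @export
flatten_decomposed <- function(decomposed) {
  if (length(decomposed) == 0) stop_arg("empty decomposition list")
  one <- function(d) {
    stopifnot(inherits(d, "decomposed_signal"))
    out <- numeric(0)
    nms <- character(0)
    for (lev in 1:5) {
      for (band in c("LFLF", "LFHF", "HFLF", "HFHF")) {
        x <- d$subbands$levels[[lev]][[band]]
        key <- sprintf("L%d.%s", lev, band)
        ph <- d$pisarenko[[key]]
        if (!is_empty_pisarenko(ph) && length(ph$dominant_freqs) > 0) {
          domf <- ph$dominant_freqs[1]
        } else domf <- 0
        if (!is_empty_pisarenko(ph)) {
          p <- ph$pseudospectrum / sum(ph$pseudospectrum)
          ent <- -sum(ifelse(p > 0, p * log(p), 0))
        } else ent <- 0
        out <- c(out, mean(x), stats::var(x), sum(x^2), domf, ent)
        nms <- c(nms, paste(key, c("mean", "var", "energy", "domfreq", "entropy"),
                            sep = "."))
      }
    }
    names(out) <- nms
    out
  }
  rows <- t(vapply(decomposed, one, numeric(100L)))
  rownames(rows) <- NULL
  rows
}

#' Fit PCA and project onto the leading components
#'
#' Centers the observation matrix by its column means, forms the sample
#' covariance, solves the symmetric eigenproblem and projects onto the top
#' `n_components` eigenvectors. Eigenvectors are sign-fixed so their
#' largest-magnitude entry is positive. Requesting more components than
#' `min(nrow - 1, ncol)` is a configuration error (no silent padding).
#'
#' @param X numeric matrix `[n_obs x n_vars]`.
#' @param n_components number of components to keep (default 83).
#' @return list with `model` (class `pca_model`: `mean_vector`, `eigenvalues`,
#'   `eigenvectors`) and `scores` (`[n_obs x n_components]`).
#' @export
pca_fit_transform <- function(X, n_components = 83) {
  X <- as.matrix(X)
  n_components <- check_count(n_components, "n_components")
  if (n_components > min(nrow(X) - 1L, ncol(X)))
    stop(errorCondition(
      sprintf("n_components = %d exceeds min(n_obs - 1, n_vars) = %d",
              n_components, min(nrow(X) - 1L, ncol(X))),
      class = c("ocuclean_config_error", "error")))
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  C <- crossprod(Xc) / (nrow(X) - 1L)
  eig <- eigen(C, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  vecs <- eig$vectors
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  model <- structure(list(mean_vector = mu, eigenvalues = vals,
                          eigenvectors = vecs), class = "pca_model")
  scores <- Xc %*% vecs[, seq_len(n_components), drop = FALSE]
  colnames(scores) <- paste0("PCA", seq_len(n_components))
  list(model = model, scores = scores)
}

#' Fit ICA by fixed-point iteration and return component activations
#'
#' The input is centered and whitened via PCA to `n_components` dimensions,
#' then a symmetric fixed-point iteration with the log-cosh contrast
#' (nonlinearity `tanh`) estimates the unmixing matrix that maximizes
#' non-Gaussianity. Rows of the unmixing matrix are unit-normalized and
#' sign-fixed (largest-magnitude entry positive). If the iteration does not
#' converge within `max_iter` a warning is emitted and the best iterate is
#' returned. Inputs whose recovered components are all indistinguishable from
#' Gaussian (log-cosh negentropy proxy below `1e-4`) are flagged
#' `non_identifiable`.
#'
#' @param X numeric matrix `[n_obs x n_vars]`.
#' @param n_components number of independent components (default 83).
#' @param seed integer seed for the random orthogonal start.
#' @param max_iter,tol fixed-point iteration controls.
#' @return list with `model` (class `ica_model`: `unmixing`,
#'   `mixing_estimate`, `component_count`, `converged`, `non_identifiable`)
#'   and `scores` (`[n_obs x n_components]` component activations).
#' @export
ica_fit_transform <- function(X, n_components = 83, seed = 1,
                              max_iter = 500, tol = 1e-6) {
  X <- as.matrix(X)
  n_components <- check_count(n_components, "n_components")
  if (n_components > min(nrow(X) - 1L, ncol(X)))
    stop(errorCondition(
      sprintf("n_components = %d exceeds min(n_obs - 1, n_vars) = %d",
              n_components, min(nrow(X) - 1L, ncol(X))),
      class = c("ocuclean_config_error", "error")))
  n <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  C <- crossprod(Xc) / (n - 1L)
  eig <- eigen(C, symmetric = TRUE)
  keep <- seq_len(n_components)
  vals <- pmax(eig$values[keep], 1e-12)
  K <- t(eig$vectors[, keep, drop = FALSE]) / sqrt(vals)   # whitening, c x p
  Z <- K %*% t(Xc)                                          # c x n, identity cov
  W <- with_seed(derive_seed(seed, "ica"), {
    M <- matrix(stats::rnorm(n_components^2), n_components)
    qr.Q(qr(M))
  })
  sym_decorrelate <- function(W) {
    s <- eigen(W %*% t(W), symmetric = TRUE)
    s$vectors %*% diag(1 / sqrt(pmax(s$values, 1e-12)), n_components) %*%
      t(s$vectors) %*% W
  }
  W <- sym_decorrelate(W)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    S <- W %*% Z
    G <- tanh(S)
    Gp <- 1 - G^2
    W_new <- (G %*% t(Z)) / n - diag(rowMeans(Gp), n_components) %*% W
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(abs(diag(W_new %*% t(W))) - 1))
    W <- W_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("ICA did not converge in %d iterations; returning best iterate",
                    max_iter))
  S <- W %*% Z
  # negentropy proxy per component: (E[logcosh(s)] - E[logcosh(gauss)])^2
  negent <- (rowMeans(log(cosh(S))) - 0.374567207491438)^2
  non_identifiable <- all(negent < 1e-4)
  unmix <- W %*% K                                           # c x p
  unmix <- unmix / sqrt(rowSums(unmix^2))
  for (j in seq_len(nrow(unmix))) {
    i <- which.max(abs(unmix[j, ]))
    if (unmix[j, i] < 0) unmix[j, ] <- -unmix[j, ]
  }
  scores <- Xc %*% t(unmix)
  colnames(scores) <- paste0("ICA", seq_len(n_components))
  mixing <- tryCatch(t(qr.solve(unmix %*% t(unmix), unmix)),
                     error = function(e) t(unmix))
  model <- structure(list(unmixing = unmix, mixing_estimate = mixing,
                          component_count = n_components,
                          converged = converged,
                          non_identifiable = non_identifiable),
                     class = "ica_model")
  list(model = model, scores = scores)
}

#' Concatenate PCA and ICA feature blocks
#'
#' @param pca_cols matrix of PCA features (may have zero columns).
#' @param ica_cols matrix of ICA features (may have zero columns).
#' @return an object of class `feature_matrix`: list with `values`
#'   (`[n_epochs x n_features]`, PCA block first), `method_tags` (per-column
#'   `"PCA"`/`"ICA"`) and `component_count`.
#' @export
concat_features <- function(pca_cols, ica_cols = NULL) {
  pca_cols <- as.matrix(pca_cols)
  if (is.null(ica_cols) || ncol(as.matrix(ica_cols)) == 0) {
    values <- pca_cols
    tags <- rep("PCA", ncol(pca_cols))
  } else {
    ica_cols <- as.matrix(ica_cols)
    if (nrow(ica_cols) != nrow(pca_cols))
      stop_arg("PCA and ICA blocks must have the same number of rows")
    values <- cbind(pca_cols, ica_cols)
    tags <- c(rep("PCA", ncol(pca_cols)), rep("ICA", ncol(ica_cols)))
  }
  if (!all(is.finite(values))) stop_arg("feature matrix contains non-finite values")
  structure(list(values = values, method_tags = tags,
                 component_count = c(PCA = sum(tags == "PCA"),
                                     ICA = sum(tags == "ICA"))),
            class = "feature_matrix")
}

#' Write a feature matrix to delimited text with tagged column names
#' @param fm a `feature_matrix`.
#' @param path output file.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- as.data.frame(fm$values)
  names(df) <- paste(fm$method_tags, seq_along(fm$method_tags), sep = "_")
  data.table::fwrite(df, path)
  invisible(path)
}
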