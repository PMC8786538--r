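# End-to-end orchestration of the two phases. Detection: per-epoch wavelet +
# Pisarenko decomposition of the channel-pooled signal, PCA/ICA features, a
# DS-EFO-tuned deformable-network classifier. Mitigation: per-channel EMCD,
# a tuned deformable-network denoiser applied to the artifact-bearing
# component, inverse EMCD reconstruction, scored against the clean target.

#' Default pipeline configuration
#'
#' Nested configuration covering every module. Unknown keys are rejected by
#' [validate_config()]; ranges are checked before any computation.
#'
#' @param seed master seed for the whole run.
#' @return nested list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1) {
  cfg <- list(
    seed = as.integer(seed),
    semisim = list(n_channels = 25L, n_epochs = 288L, fs = 250, duration = 6,
                   snr = 1.0, artifact_fraction = 0.5, amplitude_ratio = 30,
                   blink_rate = 0.5),
    decomp = list(wavelet = "db4", pisarenko_order = 8L, pisarenko_grid = 256L),
    features = list(n_components = 83L),
    split = list(train = 0.6, val = 0.1, test = 0.3),
    tuning = list(detector_pop = 6L, detector_iters = 10L,
                  denoiser_pop = 4L, denoiser_iters = 3L,
                  full_budget = FALSE),
    dcn = list(batch_size = 16L),
    mitigation = list(denoise_part = "modes", max_levels = 5L,
                      max_train_pairs = 160L)
  )
  structure(cfg, class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Checks that every key is known (unknown keys are rejected) and that ranges
#' are sane. Returns the merged configuration (missing keys take defaults).
#'
#' @param config a (possibly partial) configuration list.
#' @return a complete validated `pipeline_config`.
#' @export
validate_config <- function(config = list()) {
  ref <- default_config()
  merged <- unclass(ref)
  for (top in names(config)) {
    if (!top %in% names(ref)) stop_arg(sprintf("unknown config key '%s'", top))
    if (is.list(ref[[top]])) {
      for (k in names(config[[top]])) {
        if (!k %in% names(ref[[top]]))
          stop_arg(sprintf("unknown config key '%s$%s'", top, k))
        merged[[top]][[k]] <- config[[top]][[k]]
      }
    } else merged[[top]] <- config[[top]]
  }
  with(merged$split, {
    if (abs(train + val + test - 1) > 1e-9)
      stop_arg("split fractions must sum to 1")
  })
  if (!merged$mitigation$denoise_part %in% c("trend", "modes"))
    stop_arg("mitigation$denoise_part must be 'trend' or 'modes'")
  if (merged$semisim$snr <= 0) stop_arg("semisim$snr must be positive")
  if (isTRUE(merged$tuning$full_budget)) {
    merged$tuning$detector_pop <- 10L
    merged$tuning$detector_iters <- 100L
  }
  structure(merged, class = "pipeline_config")
}

# Cheap deterministic hash of an R object (provenance stamp).
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Seeded 60/10/30 (by default) epoch split.
split_epochs <- function(n, split, seed) {
  with_seed(derive_seed(seed, "split"), {
    ord <- sample.int(n)
    n_train <- round(split$train * n)
    n_val <- round(split$val * n)
    list(train = sort(ord[seq_len(n_train)]),
         val = sort(ord[seq(n_train + 1L, n_train + n_val)]),
         test = sort(ord[seq(n_train + n_val + 1L, n)]))
  })
}

# Channel-pooled signal (mean over EEG channels) for every epoch: n x epochs.
pooled_eeg <- function(data) {
  eeg <- which(data$channel_roles == "EEG")
  apply(data$data[eeg, , , drop = FALSE], c(2, 3), mean)
}

#' Detection-phase feature matrix for an epoch tensor
#'
#' Pools EEG channels, decomposes every epoch (wavelet cascade + Pisarenko),
#' flattens to per-subband statistics and extracts concatenated PCA/ICA
#' features.
#'
#' @param data an `epoch_tensor`.
#' @param config a validated `pipeline_config`.
#' @return a `feature_matrix` (epochs x features).
#' @export
detection_features <- function(data, config = default_config()) {
  config <- validate_config(unclass(config))
  pooled <- pooled_eeg(data)
  dcfg <- config$decomp
  dec <- lapply(seq_len(ncol(pooled)), function(e)
    decompose_epoch(pooled[, e], dcfg))
  flat <- flatten_decomposed(dec)
  nc <- config$features$n_components
  pca <- pca_fit_transform(flat, nc)
  ica <- ica_fit_transform(flat, nc, seed = derive_seed(config$seed, "ica"))
  concat_features(pca$scores, ica$scores)
}

zscore_cols <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[sd == 0] <- 1
  sweep(sweep(X, 2L, mu), 2L, sd, "/")
}

#' Run the detection phase
#'
#' Extracts features, splits epochs into train/validation/test, tunes the
#' detector's epoch count and learning rate with DS-EFO, trains the final
#' detector and predicts per-epoch labels. When ground-truth labels are
#' present a [detection_report()] is computed on the held-out test split.
#'
#' @param data an `epoch_tensor`.
#' @param config configuration (see [default_config()]).
#' @return list of class `run_result` with components `detection` (report,
#'   predicted labels, split, tuned config) and `provenance`.
#' @export
run_detection <- function(data, config = default_config()) {
  config <- validate_config(unclass(config))
  seed <- config$seed
  fm <- detection_features(data, config)
  X <- zscore_cols(fm$values)
  n <- nrow(X)
  inputs <- lapply(seq_len(n), function(i) matrix(X[i, ], nrow = 1L))
  has_labels <- !is.null(data$labels) && any(data$labels == 1L)
  sp <- split_epochs(n, config$split, seed)
  spec <- detector_spec(ncol(X))
  if (has_labels) {
    y <- as.numeric(data$labels)
    tp <- efo_params(matrix(c(10, 20, 0.1, 0.9), 2),
                     pop_size = config$tuning$detector_pop,
                     iterations = config$tuning$detector_iters,
                     seed = derive_seed(seed, "tune-det"))
    tuned <- tune_hyperparams(spec, inputs[sp$train], y[sp$train],
                              inputs[sp$val], y[sp$val], task = "detect",
                              dsefo_params = tp,
                              batch_size = config$dcn$batch_size, seed = seed)
    model <- dcn_train(spec, inputs[sp$train], y[sp$train], tuned$config)
    pred <- dcn_predict(model, inputs, "label")
    report <- detection_report(confusion(data$labels[sp$test], pred[sp$test]))
    tuned_cfg <- tuned$config
  } else {
    model <- dcn_train(spec, inputs, rep(0, n),
                       network_config(seed = derive_seed(seed, "det-train")))
    pred <- dcn_predict(model, inputs, "label")
    report <- NULL
    tuned_cfg <- NULL
  }
  structure(list(
    detection = list(report = report, predicted_labels = pred, split = sp,
                     tuned_config = tuned_cfg, model = model),
    provenance = list(config_hash = config_hash(unclass(config)), seed = seed,
                      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
    class = "run_result")
}

# EMCD split of one vector into the component handed to the denoiser and the
# component kept untouched. Default direction "modes": the oscillatory modes
# are stacked as input channels (zero-padded to max_levels) and the leftover
# trend is kept, matching the reconstruction retrieved = denoised + leftover.
# The "trend" direction flips the roles.
emcd_parts <- function(x, mcfg) {
  res <- emcd_decompose(x, mcfg$max_levels)
  n <- length(x)
  osc <- if (res$n_levels > 0) Reduce(`+`, res$modes) else numeric(n)
  if (mcfg$denoise_part == "trend") {
    list(denoise = matrix(res$leftover, nrow = 1L), keep = osc)
  } else {
    stack <- matrix(0, mcfg$max_levels, n)
    for (k in seq_len(res$n_levels)) stack[k, ] <- res$modes[[k]]
    list(denoise = stack, keep = res$leftover)
  }
}

#' Run the mitigation phase
#'
#' Each targeted epoch/channel is decomposed with EMCD; the artifact-bearing
#' component (by default the oscillatory modes, stacked as input channels —
#' blink pulses concentrate in the mid/late modes) is passed through a
#' DS-EFO-tuned deformable-network denoiser trained on the train-split
#' epochs against the clean target; the retrieved signal is the untouched
#' component plus the denoised one (inverse EMCD). Per-epoch reconstruction scores are computed against the
#' clean target alongside the contaminated-baseline scores.
#'
#' @param data an `epoch_tensor` containing the epochs to mitigate.
#' @param clean_target clean `epoch_tensor` (or `NULL` to use `data$clean`).
#' @param config configuration.
#' @param epochs epoch indices to mitigate (default: labelled contaminated).
#' @param model optional pre-trained denoiser (skips tuning/training).
#' @return list of class `run_result` with component `mitigation`:
#'   `retrieved` (an `epoch_tensor`), per-epoch `scores` and
#'   `baseline_scores` data frames, the trained `model` and the `scale` used
#'   for standardization.
#' @export
run_mitigation <- function(data, clean_target = NULL, config = default_config(),
                           epochs = NULL, model = NULL) {
  config <- validate_config(unclass(config))
  seed <- config$seed
  mcfg <- config$mitigation
  clean <- if (!is.null(clean_target)) {
    if (inherits(clean_target, "epoch_tensor")) clean_target$data else clean_target
  } else data$clean
  if (is.null(epochs)) epochs <- which(data$labels == 1L)
  eeg <- which(data$channel_roles == "EEG")
  d <- dim(data$data)

  if (is.null(model)) {
    if (is.null(clean))
      stop_arg("training the denoiser requires a clean target (clean_target or data$clean)")
    sp <- split_epochs(d[3L], config$split, seed)
    train_ep <- intersect(sp$train, epochs)
    val_ep <- intersect(sp$val, epochs)
    if (length(val_ep) == 0) val_ep <- train_ep[seq_len(min(4, length(train_ep)))]
    build_pairs <- function(eps, cap) {
      combos <- expand.grid(ch = eeg, e = eps)
      if (nrow(combos) > cap) {
        keep <- with_seed(derive_seed(seed, "pairs", length(eps)),
                          sample.int(nrow(combos), cap))
        combos <- combos[sort(keep), ]
      }
      ins <- vector("list", nrow(combos)); tgt <- vector("list", nrow(combos))
      for (i in seq_len(nrow(combos))) {
        ch <- combos$ch[i]; e <- combos$e[i]
        parts <- emcd_parts(data$data[ch, , e], mcfg)
        ins[[i]] <- parts$denoise
        tgt[[i]] <- clean[ch, , e] - parts$keep
      }
      list(inputs = ins, targets = tgt)
    }
    trn <- build_pairs(train_ep, mcfg$max_train_pairs)
    val <- build_pairs(val_ep, max(8L, mcfg$max_train_pairs %/% 4L))
    scale <- stats::sd(unlist(trn$inputs))
    if (!is.finite(scale) || scale == 0) scale <- 1
    norm <- function(p) list(inputs = lapply(p$inputs, function(x) x / scale),
                             targets = lapply(p$targets, function(x) x / scale))
    trn_n <- norm(trn); val_n <- norm(val)
    den_ch <- if (mcfg$denoise_part == "trend") 1L else mcfg$max_levels
    spec <- denoiser_spec(d[2L], input_channels = den_ch)
    tp <- efo_params(matrix(c(10, 20, 0.1, 0.9), 2),
                     pop_size = config$tuning$denoiser_pop,
                     iterations = config$tuning$denoiser_iters,
                     seed = derive_seed(seed, "tune-den"))
    tuned <- tune_hyperparams(spec, trn_n$inputs, trn_n$targets,
                              val_n$inputs, val_n$targets, task = "denoise",
                              dsefo_params = tp,
                              batch_size = config$dcn$batch_size,
                              seed = derive_seed(seed, "den"))
    fitted <- dcn_train(spec, trn_n$inputs, trn_n$targets, tuned$config)
    model <- structure(list(net = fitted, scale = scale, tuned = tuned$config),
                       class = "denoiser_model")
  }

  retrieved <- data$data
  for (e in epochs) {
    for (ch in eeg) {
      parts <- emcd_parts(data$data[ch, , e], mcfg)
      den <- dcn_forward(model$net$params, parts$denoise / model$scale)$output *
        model$scale
      retrieved[ch, , e] <- parts$keep + den
    }
  }
  score_rows <- function(sig) {
    do.call(rbind, lapply(epochs, function(e) {
      per_ch <- vapply(eeg, function(ch) {
        s <- signal_scores(sig[ch, , e], clean[ch, , e])
        c(s$mae, s$rmse, s$corr)
      }, numeric(3))
      data.frame(epoch = e, mae = mean(per_ch[1, ]), rmse = mean(per_ch[2, ]),
                 corr = mean(per_ch[3, ]))
    }))
  }
  scores <- baseline <- NULL
  if (!is.null(clean)) {
    scores <- score_rows(retrieved)
    baseline <- score_rows(data$data)
  }
  out <- epoch_tensor(retrieved, fs = data$fs, labels = data$labels,
                      channel_roles = data$channel_roles, clean = clean)
  structure(list(
    mitigation = list(retrieved = out, scores = scores,
                      baseline_scores = baseline, model = model,
                      epochs = epochs),
    provenance = list(config_hash = config_hash(unclass(config)), seed = seed,
                      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
    class = "run_result")
}

#' Run detection followed by mitigation of the predicted-artifactual epochs
#'
#' Mitigation is applied only to epochs the detector flags; epochs predicted
#' clean are never modified. With zero predicted artifacts mitigation is
#' skipped and the output equals the input.
#'
#' @param data an `epoch_tensor` (with clean target attached for training).
#' @param config configuration.
#' @return a `run_result` with both `detection` and `mitigation` components.
#' @export
run_full <- function(data, config = default_config()) {
  config <- validate_config(unclass(config))
  det <- run_detection(data, config)
  flagged <- which(det$detection$predicted_labels == 1L)
  if (length(flagged) == 0) {
    mit <- list(retrieved = data, scores = NULL, baseline_scores = NULL,
                model = NULL, epochs = integer(0))
  } else {
    mit <- run_mitigation(data, config = config, epochs = flagged)$mitigation
  }
  structure(list(detection = det$detection, mitigation = mit,
                 provenance = det$provenance),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat("<run_result>\n")
  if (!is.null(x$detection)) {
    cat(sprintf("  detection: %d epochs flagged\n",
                sum(x$detection$predicted_labels)))
    if (!is.null(x$detection$report))
      cat(sprintf("    held-out accuracy %.3f, precision %.3f\n",
                  x$detection$report$accuracy, x$detection$report$precision))
  }
  if (!is.null(x$mitigation) && !is.null(x$mitigation$scores)) {
    cat(sprintf("  mitigation: %d epochs, mean MAE %.3f (baseline %.3f), mean corr %.3f (baseline %.3f)\n",
                length(x$mitigation$epochs),
                mean(x$mitigation$scores$mae), mean(x$mitigation$baseline_scores$mae),
                mean(x$mitigation$scores$corr), mean(x$mitigation$baseline_scores$corr)))
  }
  invisible(x)
}
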