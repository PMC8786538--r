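# Internal helpers shared across modules: seeded randomness and input checks.

#' Derive a reproducible sub-seed from a master seed and a stream label
#'
#' All randomness in the package flows from a single integer seed. Independent
#' random streams (epoch selection, blink onsets, network initialization, the
#' optimizer, ...) each derive their own sub-seed by hashing the master seed
#' together with a short label, so that every fixture and every fit is
#' reproducible and streams do not interfere.
#'
#' @param seed master integer seed.
#' @param ... labels (character or numeric scalars) identifying the stream.
#' @return an integer in [0, 2^31 - 2].
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- (abs(as.numeric(seed)) + 1) %% 2147483647
  for (key in list(...)) {
    for (ch in utf8ToInt(paste0(as.character(key), "|"))) {
      h <- (h * 31 + ch) %% 2147483647
    }
  }
  as.integer(h)
}

# Evaluate `expr` under a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_arg <- function(msg) stop(errorCondition(msg, class = c("ocuclean_argument_error", "error")))

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x != round(x))
    stop_arg(sprintf("`%s` must be an integer >= %d", name, min))
  as.integer(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_arg(sprintf("`%s` must be a positive number", name))
  as.numeric(x)
}
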