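#' Derive a child seed from a master seed and stream identifiers
#'
#' Every stochastic operation in the package draws from an RNG stream whose
#' seed is derived deterministically from a master seed plus one or more
#' integer stream identifiers (record index, replicate index, method slot).
#' This makes dataset-level results invariant to processing order and keeps
#' per-record augmentation reproducible in isolation.
#'
#' @param seed master seed (integer).
#' @param ... integer stream identifiers.
#' @return An integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  ids <- c(seed, ...)
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- 104729
  for (v in ids) {
    v <- as.numeric(v) %% m
    h <- (h * 48271 + v + 1) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("emgaug_config_error", "error")))
}

stop_io <- function(...) {
  stop(errorCondition(paste0(...), class = c("emgaug_io_error", "error")))
}

stop_numeric <- function(...) {
  stop(errorCondition(paste0(...), class = c("emgaug_numeric_error", "error")))
}

assert_scalar_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_config(name, " must be a finite numeric scalar")
  if (strict && x <= lower) stop_config(name, " must be > ", lower)
  if (!strict && x < lower) stop_config(name, " must be >= ", lower)
  invisible(x)
}
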