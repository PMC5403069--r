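# Internal helpers shared across the package.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic package code funnels through this so that generator output
# is bit-reproducible and library calls never perturb user RNG streams.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stop_param <- function(...) {
  stop(errorCondition(paste0(...), class = c("octaquant_parameter_error", "octaquant_error")))
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("octaquant_validation_error", "octaquant_error")))
}

stop_io <- function(...) {
  stop(errorCondition(paste0(...), class = c("octaquant_io_error", "octaquant_error")))
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_param("`", name, "` must be a single value in [0, 1], got ", format(x))
  }
  invisible(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop_param("`", name, "` must be a single positive number, got ", format(x))
  }
  invisible(x)
}
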