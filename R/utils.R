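# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the previous
#' RNG state, so seeded internals (GP restarts, sub-sampling) never perturb the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# classed error so callers can catch specific failure modes
stop_reactbo <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "reactbo_error")))
}

assert_finite <- function(x, what) {
  if (!all(is.finite(x)))
    stop_reactbo(sprintf("non-finite values in %s", what), "reactbo_nonfinite")
  invisible(x)
}
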