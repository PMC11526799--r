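#' @keywords internal
"_PACKAGE"

# Classed error helper so callers and tests can distinguish validation
# failures (bad input data) from usage errors (bad arguments).
stop_ewat <- function(msg, class = "ewat_error", ...) {
  stop(structure(
    class = c(class, "ewat_error", "error", "condition"),
    list(message = msg, call = NULL, ...)
  ))
}

# Half-up decimal rounding for presentation (round() is round-half-even).
# Internal values are never rounded; this is applied only where a report
# prints two decimals.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run code under a temporary RNG state; the caller's stream is untouched.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_ewat("'seed' must be a single integer", "ewat_usage_error")
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
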