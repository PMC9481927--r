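# Internal helpers: structured error conditions and seeded evaluation.

#' @importFrom methods is new validObject slot
#' @importFrom stats pt rnbinom rpois rnorm rlnorm runif setNames p.adjust
#' @importFrom utils read.delim write.table packageVersion
NULL

# Condition classes map onto the CLI exit codes:
#   cortex_config_error -> 2, cortex_format_error -> 3,
#   cortex_degenerate_error -> 4.
cortexStop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "cortex_error")))
}

configError <- function(msg) cortexStop(msg, "cortex_config_error")
formatError <- function(msg) cortexStop(msg, "cortex_format_error")
degenerateError <- function(msg) cortexStop(msg, "cortex_degenerate_error")

# Evaluate `expr` under a fixed RNG state, restoring the caller's state
# afterwards so no global randomness leaks out of seeded operations.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    configError("'seed' must be a single finite integer")
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(expr)
}

checkScalar <- function(x, name, lower = -Inf, upper = Inf,
                        integer = FALSE, inclusive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    configError(sprintf("'%s' must be a single finite number", name))
  }
  ok <- if (inclusive) x >= lower && x <= upper else x > lower && x < upper
  if (!ok) {
    configError(sprintf("'%s' = %g is outside [%g, %g]", name, x, lower, upper))
  }
  if (integer && x != round(x)) {
    configError(sprintf("'%s' must be an integer (got %g)", name, x))
  }
  invisible(x)
}
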