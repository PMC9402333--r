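# Internal helpers shared across the package.

rms <- function(x) sqrt(mean(x^2))

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# whatever state the caller had. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stop_insufficient_extrema <- function(msg = "too few extrema to build envelopes") {
  stop(errorCondition(msg, class = c("emdecg_insufficient_extrema", "error", "condition")))
}

is_insufficient_extrema <- function(e) inherits(e, "emdecg_insufficient_extrema")

check_scalar <- function(x, name, lower = -Inf, upper = Inf, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name))
  if ((strict_lower && x <= lower) || (!strict_lower && x < lower) || x > upper)
    stop(sprintf("'%s' = %g is out of range", name, x))
  invisible(x)
}

# Machine-parsable key=value warning line, used by the evaluation harness.
log_kv <- function(event, ...) {
  kv <- c(event = event, ...)
  message(paste(sprintf("%s=%s", names(kv), as.character(kv)), collapse = " "))
}
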