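# Classed conditions so callers (and tests) can distinguish failure modes.

bdot_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "bdot_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

stop_range        <- function(msg, ...) bdot_stop(msg, "bdot_range_error", ...)
stop_insufficient <- function(msg, ...) bdot_stop(msg, "bdot_insufficient_data", ...)
stop_format       <- function(msg, ...) bdot_stop(msg, "bdot_format_error", ...)
stop_validation   <- function(msg, ...) bdot_stop(msg, "bdot_validation_error", ...)
stop_degenerate   <- function(msg, ...) bdot_stop(msg, "bdot_degenerate_data", ...)
stop_consistency  <- function(msg, ...) bdot_stop(msg, "bdot_consistency_error", ...)
stop_stratification <- function(msg, ...) bdot_stop(msg, "bdot_stratification_error", ...)
stop_degenerate_training <- function(msg, ...) bdot_stop(msg, "bdot_degenerate_training", ...)
stop_undefined_auc <- function(msg, ...) bdot_stop(msg, "bdot_undefined_auc", ...)

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}
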