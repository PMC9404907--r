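# Structured error conditions so callers (and tests) can distinguish
# configuration mistakes from shape/value problems and I/O failures.

stop_fr <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "fundusreg_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

stop_config <- function(msg) stop_fr("fundusreg_config_error", msg)
stop_shape  <- function(msg) stop_fr("fundusreg_shape_error", msg)
stop_value  <- function(msg) stop_fr("fundusreg_value_error", msg)
stop_io     <- function(msg) stop_fr("fundusreg_io_error", msg)
stop_format <- function(msg) stop_fr("fundusreg_format_error", msg)

# Run an expression with a temporary RNG seed, restoring the caller's RNG
# state afterwards; generators stay deterministic without clobbering the
# session RNG.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
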