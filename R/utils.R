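## Internal helpers: seeded RNG isolation, condition constructors, input coercion.

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so generators never perturb user randomness.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        },
        add = TRUE
      )
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

halokin_error <- function(msg, class, call = sys.call(-1), ...) {
  stop(structure(
    class = c(class, "halokin_error", "error", "condition"),
    list(message = msg, call = call, ...)
  ))
}

check_nonneg <- function(x, what) {
  if (any(!is.finite(x) & !is.infinite(x)) || any(is.na(x)) || any(x < 0)) {
    halokin_error(sprintf("'%s' must be non-negative and non-missing", what),
                  "halokin_validation_error")
  }
  invisible(x)
}

# Accept a kin_trace, or any data frame whose first two columns are
# time and signal; return list(time, value, channel).
as_trace_xy <- function(trace) {
  if (inherits(trace, "kin_trace")) {
    list(time = trace$time_s, value = trace$value,
         channel = attr(trace, "channel"))
  } else if (is.data.frame(trace) && ncol(trace) >= 2) {
    list(time = trace[[1]], value = trace[[2]],
         channel = if (!is.null(trace$channel)) trace$channel[1] else NA_character_)
  } else {
    halokin_error("'trace' must be a kin_trace or a data frame (time, value)",
                  "halokin_validation_error")
  }
}
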