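# Internal condition helpers. Errors carry a subclass so callers (and tests)
# can distinguish invalid arguments from data-driven failures.

bc_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "bicompete_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

stop_invalid <- function(msg) bc_stop(msg, "bicompete_invalid_argument")
stop_insufficient <- function(msg) bc_stop(msg, "bicompete_insufficient_data")
stop_fit_failure <- function(msg) bc_stop(msg, "bicompete_fit_failure")

# Undefined ratios are flagged missing (NA) with a classed warning, never
# zero-filled: zero-filling would bias downstream regressions.
undefined_ratio <- function(what) {
  warning(structure(
    class = c("bicompete_undefined_ratio", "warning", "condition"),
    list(message = sprintf("undefined ratio: %s", what), call = NULL)
  ))
  NA_real_
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
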