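# Internal helpers: tolerances, classed conditions, seed handling.

# Comparison tolerance for closed-form identities and tie detection.
.TOL_EQ <- 1e-12
# Validation tolerance for inputs like 1 + 1e-10 arising from upstream
# arithmetic; such values are accepted and clamped to the unit interval.
.TOL_VALID <- 1e-9

.stop_samclone <- function(msg, class, call. = FALSE, ...) {
  stop(structure(
    class = c(class, "samclone_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

.warn_samclone <- function(msg, class, ...) {
  warning(structure(
    class = c(class, "samclone_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

# Validate a numeric vector lies in [0, 1] up to .TOL_VALID and clamp.
.check_fraction <- function(value, name, n = NULL) {
  if (!is.numeric(value) || anyNA(value)) {
    .stop_samclone(sprintf("'%s' must be numeric and non-missing", name),
                   "samclone_invalid_parameter")
  }
  if (!is.null(n) && length(value) != n) {
    .stop_samclone(sprintf("'%s' must have length %d", name, n),
                   "samclone_invalid_parameter")
  }
  if (any(value < -.TOL_VALID | value > 1 + .TOL_VALID)) {
    .stop_samclone(
      sprintf("'%s' must lie in [0, 1]; got %s", name,
              paste(format(value[value < -.TOL_VALID | value > 1 + .TOL_VALID]),
                    collapse = ", ")),
      "samclone_invalid_parameter")
  }
  pmin(pmax(value, 0), 1)
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}
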