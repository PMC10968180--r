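# Internal validation helpers shared across modules.

abort_bad <- function(...) stop(..., call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0 && x == round(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_fraction <- function(x, name, closed_upper = TRUE) {
  hi_ok <- if (closed_upper) x <= 1 else x < 1
  if (!is_number(x) || x < 0 || !hi_ok) {
    abort_bad(sprintf("`%s` must be a single number in [0, %s].",
                      name, if (closed_upper) "1]" else "1)"))
  }
  invisible(x)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's stream.
# A NULL seed leaves the global stream untouched.
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(seed, force(code))
}
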