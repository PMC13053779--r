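# internal argument checks; all user-facing errors funnel through rlang::abort

check_number <- function(x, name, min = -Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || anyNA(x)) {
    abort(sprintf("`%s` must be numeric with no missing values.", name))
  }
  lo <- if (allow_zero) min else min + .Machine$double.eps
  if (any(x < lo)) {
    abort(sprintf("`%s` must be >= %s.", name, format(min)))
  }
  invisible(x)
}

check_same_length <- function(x, y, xname, yname) {
  if (length(x) != length(y)) {
    abort(sprintf("`%s` and `%s` must have the same length.", xname, yname))
  }
  invisible(NULL)
}

# run code with a locally-set RNG seed, leaving the global stream untouched;
# a NULL seed uses (and advances) the current stream
with_seed_or_not <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}
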