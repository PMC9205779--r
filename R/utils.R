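# internal helpers shared across modules

# run `code` under a fixed RNG seed without disturbing the caller's RNG state;
# seed = NULL leaves the current stream untouched
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# error function (base R exposes only pnorm)
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number.", name))
  }
  invisible(x)
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a fraction in [0, 1].", name))
  }
  invisible(x)
}

# euclidean distance between two rows of (x, y); positions may instead be
# one-dimensional arclength s
step_lengths <- function(x, y = NULL) {
  if (is.null(y)) abs(diff(x)) else sqrt(diff(x)^2 + diff(y)^2)
}

point_distance <- function(x1, y1, x2, y2) sqrt((x2 - x1)^2 + (y2 - y1)^2)
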