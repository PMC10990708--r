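#' Robust noise-sigma estimate from successive differences
#'
#' Estimates the standard deviation of additive noise in a piecewise-constant
#' signal from the median absolute successive difference. Differencing removes
#' the (locally constant) signal; the median absorbs the few frames that span
#' a genuine step. For Gaussian noise, `sd(diff(x)) = sqrt(2) * sigma`, and
#' `median(|z|) = qnorm(0.75) * sd(z)` for centered Gaussian `z`.
#'
#' @param x Numeric intensity series (length >= 2).
#' @return Non-negative noise sigma estimate (0 for a constant series).
#' @export
#' @examples
#' estimate_noise_sigma(rnorm(500, sd = 2)) # ~2
estimate_noise_sigma <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2)
  stats::median(abs(diff(x))) / (sqrt(2) * stats::qnorm(0.75))
}

# shared argument checks ------------------------------------------------------

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single finite number in [0, 1].", name),
          class = "svfusion_parameter_error")
  }
  invisible(x)
}

check_positive_rate <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single finite positive rate.", name),
          class = "svfusion_parameter_error")
  }
  invisible(x)
}

check_rate_order <- function(k_fast, k_slow) {
  check_positive_rate(k_fast, "k_fast")
  check_positive_rate(k_slow, "k_slow")
  if (k_fast < k_slow) {
    abort("`k_fast` must be >= `k_slow`.", class = "svfusion_parameter_error")
  }
  invisible(TRUE)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < min || x != floor(x)) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min),
          class = "svfusion_parameter_error")
  }
  invisible(as.integer(x))
}

# Run thunk under a locally-seeded RNG, restoring global state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
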