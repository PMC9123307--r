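# Internal helpers: argument checking, seeded evaluation, HDI.

abort <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "synq_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE,
                         integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("`%s` must be a single finite number", name),
          "synq_parameter_error")
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    abort(sprintf(
      "`%s` = %g is outside the allowed range %s%g, %g%s", name, x,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]"), "synq_parameter_error")
  if (integer && x != round(x))
    abort(sprintf("`%s` must be an integer", name), "synq_parameter_error")
  x
}

#' Evaluate code with a fixed RNG seed
#'
#' All generators route their randomness through this helper so that a fixed
#' seed gives bit-identical output without disturbing the caller's RNG state.
#' @noRd
with_seed <- function(seed, code) {
  check_number(seed, "seed", integer = TRUE)
  withr::with_seed(as.integer(seed), code)
}

#' Highest density interval of a sample
#'
#' Shortest interval containing `prob` of the draws (empirical HDI as used for
#' posterior summaries).
#'
#' @param x numeric vector of draws.
#' @param prob mass to cover, default 0.95.
#' @return numeric length-2 vector `c(lower, upper)`.
#' @export
hdi <- function(x, prob = 0.95) {
  check_number(prob, "prob", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 2L) abort("need at least 2 finite draws for an HDI", "synq_contract_error")
  m <- max(1L, floor(prob * n))
  if (m >= n) return(c(x[1L], x[n]))
  widths <- x[(m + 1L):n] - x[1L:(n - m)]
  i <- which.min(widths)
  c(x[i], x[i + m])
}

# row-major ordering key for (row, col) pairs
order_row_major <- function(row, col) order(row, col)
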