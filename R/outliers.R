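# Univariate outlier gating with Monte-Carlo-calibrated cutoffs.
#
# A point is flagged when it falls outside mean +/- c(n) * SD, where c(n) is
# calibrated by simulation so that a clean Gaussian sample of size n is
# flagged anywhere with probability exactly 1 - alpha (family-wise).

#' Outlier-detection specification
#'
#' @param alpha confidence coefficient (default 0.95): the probability that
#'   a clean Gaussian sample produces no flag at all.
#' @param n_min,n_max calibrated sample-size range (default 3-100).
#' @param n_reps Monte-Carlo replicates per sample size used to calibrate
#'   the cutoff.
#' @param seed base seed of the calibration simulation (the per-size seed is
#'   `seed + n`); cutoffs are cached per (n, alpha, n_reps, seed).
#' @return an object of class `outlier_spec`.
#' @export
outlier_spec <- function(alpha = 0.95, n_min = 3, n_max = 100,
                         n_reps = 50000, seed = 1234) {
  check_number(alpha, "alpha", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(n_min, "n_min", lower = 3, integer = TRUE)
  check_number(n_max, "n_max", lower = n_min, integer = TRUE)
  check_number(n_reps, "n_reps", lower = 1000, integer = TRUE)
  check_number(seed, "seed", integer = TRUE)
  structure(list(alpha = alpha, n_min = as.integer(n_min),
                 n_max = as.integer(n_max), n_reps = as.integer(n_reps),
                 seed = as.integer(seed)),
            class = "outlier_spec")
}

#' Calibrated outlier cutoff for a sample size
#'
#' `c(n)` is the `alpha` quantile of `max_i |x_i - mean| / sd` over
#' `n_reps` simulated standard-Gaussian samples of size `n`.
#'
#' @param n sample size within the spec's calibrated range.
#' @param spec an [outlier_spec()].
#' @return the cutoff in SD units.
#' @export
outlier_cutoff <- function(n, spec = outlier_spec()) {
  stopifnot(inherits(spec, "outlier_spec"))
  check_number(n, "n", integer = TRUE)
  if (n < spec$n_min || n > spec$n_max)
    abort(sprintf(
      "n = %d is outside the calibrated range [%d, %d]; recalibrate with outlier_spec(n_min=, n_max=)",
      n, spec$n_min, spec$n_max), "synq_calibration_error")
  key <- sprintf("outcut_%d_%g_%d_%d", n, spec$alpha, spec$n_reps, spec$seed)
  if (!is.null(.synq_cache[[key]])) return(.synq_cache[[key]])
  cutoff <- with_seed(spec$seed + n, {
    m <- matrix(rnorm(spec$n_reps * n), spec$n_reps, n)
    ctr <- m - rowMeans(m)
    rsd <- sqrt(rowSums(ctr^2) / (n - 1))
    maxz <- apply(abs(ctr), 1L, max) / rsd
    unname(quantile(maxz, spec$alpha))
  })
  .synq_cache[[key]] <- cutoff
  cutoff
}

#' Flag outliers in one group's samples
#'
#' @param x numeric sample (n >= 3).
#' @param spec an [outlier_spec()].
#' @return logical flags, one per sample; `attr(, "cutoff_sd")` carries the
#'   calibrated cutoff used.
#' @export
detect_outliers <- function(x, spec = outlier_spec()) {
  if (!is.numeric(x) || length(x) < 3L)
    abort("outlier detection needs at least 3 samples", "synq_contract_error")
  cutoff <- outlier_cutoff(length(x), spec)
  s <- sd(x)
  flags <- if (s > 0) abs(x - mean(x)) > cutoff * s else rep(FALSE, length(x))
  structure(flags, cutoff_sd = cutoff)
}
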