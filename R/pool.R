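# Readily-releasable-pool estimation from stimulus trains:
# sweep quality control and back-extrapolation of the cumulative amplitudes.

#' Quality-control filter for train sweeps
#'
#' Removes AP-flagged sweeps and rejects the whole recording (with a
#' machine-readable reason) when fewer than `min_sweeps` sweeps survive or
#' when any sweep's series resistance exceeds `max_rs_mohm`. Rejection is an
#' error of class `synq_qc_rejection` carrying `reason` equal to
#' `"too_few_sweeps"` or `"high_series_resistance"` — never a silent empty
#' recording.
#'
#' @param recording a [train_recording()].
#' @param min_sweeps minimum surviving sweep count (default 10).
#' @param max_rs_mohm series resistance limit, MOhm (default 30).
#' @return the filtered `train_recording`.
#' @export
qc_filter_sweeps <- function(recording, min_sweeps = 10, max_rs_mohm = 30) {
  stopifnot(inherits(recording, "train_recording"))
  check_number(min_sweeps, "min_sweeps", lower = 1, integer = TRUE)
  check_number(max_rs_mohm, "max_rs_mohm", lower = 0, strict_lower = TRUE)
  if (any(recording$rs_mohm > max_rs_mohm))
    abort(sprintf("recording rejected: series resistance %.1f MOhm exceeds %g MOhm",
                  max(recording$rs_mohm), max_rs_mohm),
          "synq_qc_rejection", reason = "high_series_resistance")
  keep <- !recording$has_ap
  if (sum(keep) < min_sweeps)
    abort(sprintf("recording rejected: only %d sweeps after AP removal (need >= %d)",
                  sum(keep), min_sweeps),
          "synq_qc_rejection", reason = "too_few_sweeps")
  out <- recording
  out$amplitudes <- recording$amplitudes[keep, , drop = FALSE]
  out$rs_mohm <- recording$rs_mohm[keep]
  out$has_ap <- recording$has_ap[keep]
  out
}

#' Estimate the readily releasable pool by back-extrapolation
#'
#' Amplitudes are averaged across sweeps per stimulus, cumulated, and an
#' unweighted ordinary least squares line is fit to the cumulative amplitude
#' over the stimuli in `fit_window` (default 90-100, i.e. the last 11 points
#' of a 100-pulse train, where depression has reached steady state). The
#' y-intercept estimates the effective pool (pA); the slope is the vesicle
#' recruitment rate (pA/stimulus). The averaged cumulative plot is fit once
#' (not per sweep).
#'
#' @param recording a QC-passed [train_recording()].
#' @param fit_window inclusive stimulus index range `c(first, last)`.
#' @return an object of class `pool_estimate` with fields `rrp_pa`,
#'   `replenishment_pa_per_stim`, `fit_window`, `r_squared`, and the averaged
#'   `cumulative` curve.
#' @export
estimate_pools <- function(recording, fit_window = c(90, 100)) {
  stopifnot(inherits(recording, "train_recording"))
  if (length(fit_window) != 2L || any(fit_window != round(fit_window)) ||
      fit_window[1] < 1 || fit_window[2] > recording$n_pulses ||
      fit_window[1] >= fit_window[2])
    abort(sprintf("fit window must be an increasing integer pair within [1, %d]",
                  recording$n_pulses), "synq_contract_error")
  mean_amp <- colMeans(recording$amplitudes)
  cum <- cumsum(mean_amp)
  n <- fit_window[1]:fit_window[2]
  fit <- lm(cum[n] ~ n)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((cum[n] - mean(cum[n]))^2)
  structure(list(rrp_pa = unname(coef(fit)[1]),
                 replenishment_pa_per_stim = unname(coef(fit)[2]),
                 fit_window = as.integer(fit_window),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 cumulative = cum),
            class = "pool_estimate")
}

#' @export
print.pool_estimate <- function(x, ...) {
  cat(sprintf(
    "<pool_estimate> RRP %.1f pA, replenishment %.2f pA/stimulus (fit %d-%d, R^2 %.4f)\n",
    x$rrp_pa, x$replenishment_pa_per_stim, x$fit_window[1], x$fit_window[2],
    x$r_squared))
  invisible(x)
}
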