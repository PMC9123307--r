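# Synthetic electrophysiology: depressing stimulus trains, miniature-event
# traces, and wideband LFP with embedded spikes.

#' Construct a train recording
#'
#' Container for repeated stimulus-train sweeps: an amplitude matrix (one row
#' per sweep, one column per stimulus) plus per-sweep series resistance and
#' action-potential flags.
#'
#' @param amplitudes numeric matrix, sweeps x pulses (pA).
#' @param rate_hz stimulation rate, Hz.
#' @param rs_mohm per-sweep series resistance, MOhm (recycled).
#' @param has_ap per-sweep logical action-potential flag (recycled).
#' @return an object of class `train_recording`.
#' @export
train_recording <- function(amplitudes, rate_hz = 20, rs_mohm = 15,
                            has_ap = FALSE) {
  amplitudes <- as.matrix(amplitudes)
  if (!is.numeric(amplitudes) || !nrow(amplitudes))
    abort("`amplitudes` must be a non-empty numeric matrix", "synq_parameter_error")
  check_number(rate_hz, "rate_hz", lower = 0, strict_lower = TRUE)
  structure(list(amplitudes = unname(amplitudes),
                 rs_mohm = rep_len(as.numeric(rs_mohm), nrow(amplitudes)),
                 has_ap = rep_len(as.logical(has_ap), nrow(amplitudes)),
                 rate_hz = rate_hz, n_pulses = ncol(amplitudes)),
            class = "train_recording")
}

#' @export
print.train_recording <- function(x, ...) {
  cat(sprintf("<train_recording> %d sweeps x %d pulses at %g Hz (%d AP-flagged)\n",
              nrow(x$amplitudes), x$n_pulses, x$rate_hz, sum(x$has_ap)))
  invisible(x)
}

# Noiseless amplitudes of the depletion model, closed form.
train_closed_form <- function(spec) {
  dt <- 1 / spec$rate_hz
  n_ss <- spec$r_replenish * dt / spec$p_release
  k <- seq_len(spec$n_pulses)
  a <- spec$q_amp * spec$p_release *
    (n_ss + (spec$n0 - n_ss) * (1 - spec$p_release)^(k - 1))
  list(amplitudes = a, n_ss = n_ss,
       rrp_pa = spec$q_amp * (spec$n0 - n_ss),
       slope_pa_per_stim = spec$q_amp * spec$r_replenish * dt)
}

#' Simulate a depressing 20 Hz stimulus train
#'
#' Vesicle-depletion recursion per pulse `k`: `released = p * N_k`,
#' `A_k = q * released + noise`, `N_{k+1} = N_k - released + r * dt`. The pool
#' is not capped at `n0` (replenishment over a 5 s train is small relative to
#' the resting pool). Sweep-to-sweep variability is i.i.d. additive Gaussian
#' noise per pulse; no run-down is modelled.
#'
#' @param spec a [train_sim_spec()].
#' @param seed integer seed.
#' @param rs_mohm,has_ap per-sweep metadata forwarded to [train_recording()].
#' @return a `train_recording` with a `truth` attribute holding the noiseless
#'   amplitude vector, steady-state pool, and the closed-form back-extrapolation
#'   targets (`rrp_pa`, `slope_pa_per_stim`).
#' @export
simulate_train <- function(spec, seed, rs_mohm = 15, has_ap = FALSE) {
  stopifnot(inherits(spec, "train_sim_spec"))
  truth <- train_closed_form(spec)
  rec <- with_seed(seed, {
    noiseless <- matrix(truth$amplitudes, nrow = spec$n_sweeps,
                        ncol = spec$n_pulses, byrow = TRUE)
    amp <- noiseless + matrix(rnorm(spec$n_sweeps * spec$n_pulses,
                                    0, spec$noise_sd),
                              spec$n_sweeps, spec$n_pulses)
    train_recording(amp, rate_hz = spec$rate_hz, rs_mohm = rs_mohm,
                    has_ap = has_ap)
  })
  attr(rec, "truth") <- truth
  rec
}

# Peak-normalized difference-of-exponentials transient sampled at fs.
mini_kernel <- function(tau_rise_s, tau_decay_s, fs) {
  t_peak <- tau_rise_s * tau_decay_s / (tau_decay_s - tau_rise_s) *
    log(tau_decay_s / tau_rise_s)
  t <- seq(0, t_peak + 8 * tau_decay_s, by = 1 / fs)
  k <- exp(-t / tau_decay_s) - exp(-t / tau_rise_s)
  k / max(k)
}

#' Simulate a miniature-PSC trace
#'
#' Events from a homogeneous Poisson process; each event is a peak-normalized
#' difference-of-exponentials transient scaled by its amplitude and added
#' negatively (inward current) to Gaussian baseline noise.
#'
#' @param spec a [mini_train_spec()].
#' @param seed integer seed.
#' @return list with `trace` (pA), `fs_hz`, and `truth` — a data frame of
#'   event `time_s` (strictly inside the trace) and positive `amplitude_pa`.
#' @export
simulate_mini_trace <- function(spec, seed) {
  stopifnot(inherits(spec, "mini_train_spec"))
  with_seed(seed, {
    n_samp <- as.integer(round(spec$duration_s * spec$fs_hz))
    trace <- rnorm(n_samp, 0, spec$noise_sd)
    n_ev <- rpois(1, spec$event_rate_hz * spec$duration_s)
    times <- sort(runif(n_ev, 0, spec$duration_s))
    amps <- pmax(rnorm(n_ev, spec$amp_mean, spec$amp_sd), 0.05 * spec$amp_mean)
    if (n_ev > 0) {
      ker <- mini_kernel(spec$tau_rise_ms / 1000, spec$tau_decay_ms / 1000,
                         spec$fs_hz)
      for (i in seq_len(n_ev)) {
        i0 <- as.integer(round(times[i] * spec$fs_hz)) + 1L
        idx <- i0:min(n_samp, i0 + length(ker) - 1L)
        if (idx[1] > n_samp) next
        trace[idx] <- trace[idx] - amps[i] * ker[seq_along(idx)]
      }
    }
    list(trace = trace, fs_hz = spec$fs_hz,
         truth = data.frame(time_s = times, amplitude_pa = amps))
  })
}

#' Extracellular spike template
#'
#' Canonical negative-going biphasic waveform (sharp negative lobe with a
#' slower positive after-potential), peak-normalized to -1 at t = 0.
#'
#' @param fs_hz sampling rate.
#' @return list with `wave` and the 0-based index `peak_idx` of the negative
#'   peak within the waveform.
#' @export
spike_template <- function(fs_hz) {
  t <- seq(-0.0008, 0.002, by = 1 / fs_hz)
  w <- -exp(-t^2 / (2 * 0.0001^2)) +
    0.25 * exp(-(t - 0.0006)^2 / (2 * 0.0003^2))
  w <- w / abs(min(w))
  list(wave = w, peak_idx = which.min(w) - 1L)
}

#' Simulate a wideband LFP trace with embedded spikes
#'
#' Deterministic sinusoidal band components (zero phase) plus white Gaussian
#' noise plus negative-going spike templates at the stated times, each scaled
#' to `spike_amp_sd_units` multiples of the noise SD.
#'
#' @param spec an [lfp_spec()].
#' @param seed integer seed.
#' @return list with `trace`, `fs_hz`, and `truth` — a data frame of sorted
#'   spike `time_s`, `amp_sd_units`, and `above_exclusion` (TRUE when the
#'   planted magnitude exceeds the 30 SD artifact limit).
#' @export
simulate_lfp <- function(spec, seed) {
  stopifnot(inherits(spec, "lfp_spec"))
  with_seed(seed, {
    n_samp <- as.integer(round(spec$duration_s * spec$fs_hz))
    t <- (seq_len(n_samp) - 1L) / spec$fs_hz
    trace <- numeric(n_samp)
    for (cmp in spec$components)
      trace <- trace + cmp[2] * sin(2 * pi * cmp[1] * t)
    trace <- trace + rnorm(n_samp, 0, spec$noise_sd)
    tmpl <- spike_template(spec$fs_hz)
    for (i in seq_along(spec$spike_times_s)) {
      i0 <- as.integer(round(spec$spike_times_s[i] * spec$fs_hz)) + 1L -
        tmpl$peak_idx
      idx <- max(1L, i0):min(n_samp, i0 + length(tmpl$wave) - 1L)
      trace[idx] <- trace[idx] +
        spec$spike_amp_sd_units[i] * spec$noise_sd *
        tmpl$wave[idx - i0 + 1L]
    }
    truth <- data.frame(time_s = spec$spike_times_s,
                        amp_sd_units = if (length(spec$spike_times_s))
                          spec$spike_amp_sd_units else numeric(),
                        above_exclusion = if (length(spec$spike_times_s))
                          spec$spike_amp_sd_units > 30 else logical())
    list(trace = trace, fs_hz = spec$fs_hz, truth = truth)
  })
}
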