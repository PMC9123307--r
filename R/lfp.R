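# LFP band power (multitaper) and extracellular spike detection.

# The printed band table: closed intervals in Hz. Frequency bins falling in
# the gaps between bands (e.g. 3-4 Hz) belong to no band and are excluded
# from the total as well.
lfp_bands <- function() {
  list(delta = c(1, 3), theta = c(4, 10), alpha = c(11, 15),
       beta = c(16, 30), low_gamma = c(31, 70), high_gamma = c(71, 100))
}

#' Band-resolved LFP power
#'
#' The wideband trace is band-pass filtered 0.1-250 Hz, decimated, and its
#' multitaper PSD (DPSS tapers; 2 s windows, 50% overlap, time-bandwidth 3,
#' 5 tapers by default) is integrated over the closed frequency intervals
#' delta 1-3, theta 4-10, alpha 11-15, beta 16-30, low gamma 31-70 and high
#' gamma 71-100 Hz. `total_power` is the sum of the six band powers; bins in
#' the gaps between the printed bands count toward neither a band nor the
#' total.
#'
#' @param trace numeric voltage trace.
#' @param fs_hz sampling rate (default 20 kHz).
#' @param window_s,overlap,nw,k multitaper parameters.
#' @return an object of class `band_power`: named `power` per band,
#'   `total_power`, `relative` (power / total), and the PSD resolution
#'   `df_hz`.
#' @export
band_power <- function(trace, fs_hz = 20000, window_s = 2, overlap = 0.5,
                       nw = 3, k = 5) {
  check_number(fs_hz, "fs_hz", lower = 0, strict_lower = TRUE)
  if (!is.numeric(trace) || length(trace) < window_s * fs_hz)
    abort(sprintf("trace too short for the taper window: need at least %g s",
                  window_s), "synq_contract_error")
  x <- fft_bandpass(trace, fs_hz, lo = 0.1, hi = min(250, 0.99 * fs_hz / 2))
  factor <- max(1L, as.integer(fs_hz %/% 512))
  xd <- x[seq(1L, length(x), by = factor)]
  fs_d <- fs_hz / factor
  spec <- multitaper_psd(xd, fs_d, window_s = window_s, overlap = overlap,
                         nw = nw, k = k)
  bands <- lfp_bands()
  power <- vapply(bands, function(b) {
    sel <- spec$freq_hz >= b[1] - 1e-9 & spec$freq_hz <= b[2] + 1e-9
    sum(spec$psd[sel]) * spec$df_hz
  }, numeric(1))
  total <- sum(power)
  structure(list(power = power, total_power = total,
                 relative = if (total > 0) power / total else power * NA,
                 df_hz = spec$df_hz),
            class = "band_power")
}

#' @export
print.band_power <- function(x, ...) {
  cat("<band_power> (units^2)\n")
  print(round(x$power, 6))
  cat(sprintf("total (1-100 Hz): %g\n", x$total_power))
  invisible(x)
}

#' Detect extracellular spikes by amplitude thresholding
#'
#' The wideband signal is band-pass filtered 0.3-3 kHz and thresholded in
#' the negative range at `threshold_sd` (default 5) times the noise SD,
#' estimated robustly as `median(|signal|) / 0.6745` (configurable to the
#' plain SD). Peaks whose magnitude exceeds `exclude_sd` (default 30) times
#' the noise SD are discarded as artifacts. A waveform snippet spanning -0.5
#' to +3 ms around each negative peak is extracted.
#'
#' @param trace numeric wideband trace.
#' @param fs_hz sampling rate; at least 10 kHz.
#' @param threshold_sd detection threshold, noise-SD multiples.
#' @param exclude_sd artifact exclusion limit, noise-SD multiples.
#' @param dead_time_ms refractory dead time between detected peaks.
#' @param robust_sd use the robust noise estimator (default) or plain `sd`.
#' @return an object of class `spike_detection`: sorted `spike_times_s`,
#'   `n_spikes`, `firing_rate_hz`, `noise_sd`, `waveforms` (one row per
#'   spike, `round(0.0035 * fs) + 1` columns, NA-padded at trace edges) and
#'   `excluded_times_s` (artifact peaks above the exclusion limit).
#' @export
detect_spikes <- function(trace, fs_hz = 20000, threshold_sd = 5,
                          exclude_sd = 30, dead_time_ms = 1,
                          robust_sd = TRUE) {
  check_number(fs_hz, "fs_hz", lower = 10000)
  if (!is.numeric(trace) || length(trace) < fs_hz / 10)
    abort("trace too short for spike detection", "synq_contract_error")
  check_number(threshold_sd, "threshold_sd", lower = 0, strict_lower = TRUE)
  check_number(exclude_sd, "exclude_sd", lower = threshold_sd)

  # clipped (saturated) samples: long runs pinned at the global extremes
  runs <- rle(trace)
  clipped_lengths <- runs$lengths[runs$lengths >= 5 &
                                    (runs$values == max(trace) |
                                       runs$values == min(trace))]
  clip_mask <- logical(length(trace))
  if (length(clipped_lengths)) {
    warning("clipped regions detected; excluding them from spike detection")
    ends <- cumsum(runs$lengths)
    bad <- runs$lengths >= 5 & (runs$values == max(trace) |
                                  runs$values == min(trace))
    for (i in which(bad)) clip_mask[(ends[i] - runs$lengths[i] + 1L):ends[i]] <- TRUE
  }

  if (all(clip_mask))
    abort("trace is entirely clipped", "synq_contract_error")
  xf <- fft_bandpass(trace, fs_hz, lo = 300, hi = min(3000, 0.99 * fs_hz / 2))
  noise_sd <- if (robust_sd) median(abs(xf[!clip_mask])) / 0.6745
              else sd(xf[!clip_mask])
  thr <- threshold_sd * noise_sd
  lim <- exclude_sd * noise_sd

  below <- xf < -thr & !clip_mask
  snip_len <- as.integer(round(0.0035 * fs_hz)) + 1L
  pre_n <- as.integer(round(0.0005 * fs_hz))
  if (!any(below))
    return(structure(list(spike_times_s = numeric(), n_spikes = 0L,
                          firing_rate_hz = 0,
                          noise_sd = noise_sd,
                          waveforms = matrix(numeric(), 0, snip_len),
                          excluded_times_s = numeric()),
                     class = "spike_detection"))
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- cbind(starts[r$values], ends[r$values])
  peaks <- apply(seg, 1L, function(s) s[1] - 1L + which.min(xf[s[1]:s[2]]))
  peaks <- sort(peaks)

  dead <- as.integer(round(dead_time_ms / 1000 * fs_hz))
  keep <- rep(TRUE, length(peaks))
  i <- 1L
  while (i < length(peaks)) {
    j <- i + 1L
    while (j <= length(peaks) && peaks[j] - peaks[i] < dead) {
      if (xf[peaks[j]] < xf[peaks[i]]) { keep[i] <- FALSE; i <- j }
      else keep[j] <- FALSE
      j <- j + 1L
    }
    i <- j
  }
  peaks <- peaks[keep]

  too_big <- abs(xf[peaks]) > lim
  excluded <- peaks[too_big]
  peaks <- peaks[!too_big]

  waveforms <- matrix(NA_real_, length(peaks), snip_len)
  offs <- seq(-pre_n, length.out = snip_len)
  for (i in seq_along(peaks)) {
    idx <- peaks[i] + offs
    ok <- idx >= 1L & idx <= length(xf)
    waveforms[i, ok] <- xf[idx[ok]]
  }
  structure(list(spike_times_s = (peaks - 1L) / fs_hz,
                 n_spikes = length(peaks),
                 firing_rate_hz = length(peaks) / (length(trace) / fs_hz),
                 noise_sd = noise_sd, waveforms = waveforms,
                 excluded_times_s = (excluded - 1L) / fs_hz),
            class = "spike_detection")
}

#' @export
print.spike_detection <- function(x, ...) {
  cat(sprintf("<spike_detection> %d spikes, %.2f Hz (noise SD %.3g, %d artifact peaks excluded)\n",
              x$n_spikes, x$firing_rate_hz, x$noise_sd,
              length(x$excluded_times_s)))
  invisible(x)
}
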