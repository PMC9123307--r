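# Signal-processing primitives shared by the mini-event and LFP modules:
# zero-phase FFT filtering, DPSS (Slepian) tapers, multitaper PSD.

#' Zero-phase FFT band-pass filter
#'
#' Filters a real trace in the frequency domain with a raised-cosine
#' transition band centred on each stated edge, which gives exactly zero phase
#' shift (event and spike times are not displaced). The trace is
#' reflection-padded before transforming to suppress wrap-around transients.
#'
#' @param x numeric trace.
#' @param fs sampling rate, Hz.
#' @param lo,hi band edges in Hz; `NULL` disables the corresponding edge
#'   (`lo = NULL` gives a pure low-pass, `hi = NULL` a pure high-pass).
#' @param transition_frac transition-band width as a fraction of each edge
#'   frequency (gain is 0.5 at the stated edge).
#' @return filtered numeric trace, same length as `x`.
#' @export
fft_bandpass <- function(x, fs, lo = NULL, hi = NULL, transition_frac = 0.2) {
  n <- length(x)
  if (n < 8L) abort("trace too short to filter", "synq_contract_error")
  check_number(fs, "fs", lower = 0, strict_lower = TRUE)
  if (!is.null(hi)) check_number(hi, "hi", lower = 0, upper = fs / 2,
                                 strict_lower = TRUE)
  if (!is.null(lo)) check_number(lo, "lo", lower = 0, strict_lower = TRUE)

  np <- min(n, max(16L, as.integer(round(fs))))
  xp <- c(rev(x[seq_len(np)]), x, rev(x[(n - np + 1L):n]))
  nfft <- nextn(length(xp), c(2L, 3L, 5L))
  xp <- c(xp, numeric(nfft - length(xp)))

  f <- (seq_len(nfft) - 1L) * fs / nfft
  f <- pmin(f, fs - f)                      # fold to |f|
  gain <- rep(1, nfft)
  smooth_step <- function(f, edge, width) { # 0 below, 1 above, cosine ramp
    t <- (f - (edge - width / 2)) / width
    t <- pmin(pmax(t, 0), 1)
    0.5 * (1 - cos(pi * t))
  }
  if (!is.null(lo)) gain <- gain * smooth_step(f, lo, max(lo * transition_frac, fs / nfft))
  if (!is.null(hi)) gain <- gain * (1 - smooth_step(f, hi, max(hi * transition_frac, fs / nfft)))

  y <- Re(fft(fft(xp) * gain, inverse = TRUE)) / nfft
  y[(np + 1L):(np + n)]
}

#' Discrete prolate spheroidal sequence (Slepian) tapers
#'
#' Computed from the symmetric tridiagonal formulation (eigenvectors belonging
#' to the `k` largest eigenvalues); tapers are orthonormal.
#'
#' @param n taper length in samples.
#' @param nw time-bandwidth product.
#' @param k number of tapers (at most `2*nw - 1` is sensible).
#' @return an `n` x `k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw = 3, k = 5) {
  check_number(n, "n", lower = 8, integer = TRUE)
  check_number(nw, "nw", lower = 0.5)
  check_number(k, "k", lower = 1, upper = n, integer = TRUE)
  key <- sprintf("dpss_%d_%g_%d", n, nw, k)
  if (!is.null(.synq_cache[[key]])) return(.synq_cache[[key]])

  w <- nw / n
  i <- 0:(n - 1)
  diag_v <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off_v <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  m <- matrix(0, n, n)
  m[cbind(i + 1, i + 1)] <- diag_v
  m[cbind(1:(n - 1), 2:n)] <- off_v
  m[cbind(2:n, 1:(n - 1))] <- off_v
  ev <- eigen(m, symmetric = TRUE)
  tapers <- ev$vectors[, seq_len(k), drop = FALSE]
  # sign convention: each taper starts non-negative on average
  for (j in seq_len(k)) if (sum(tapers[, j]) < 0) tapers[, j] <- -tapers[, j]
  .synq_cache[[key]] <- tapers
  tapers
}

#' Multitaper power spectral density
#'
#' Welch-style segmentation (50% overlap by default) with DPSS tapers averaged
#' per segment; the one-sided PSD is returned in units^2/Hz.
#'
#' @param x numeric trace.
#' @param fs sampling rate, Hz.
#' @param window_s segment length, seconds.
#' @param overlap fractional segment overlap in `[0, 1)`.
#' @param nw time-bandwidth product.
#' @param k number of tapers.
#' @return list with `freq_hz`, `psd` and the frequency bin width `df_hz`.
#' @export
multitaper_psd <- function(x, fs, window_s = 2, overlap = 0.5, nw = 3, k = 5) {
  len <- as.integer(round(window_s * fs))
  if (length(x) < len)
    abort(sprintf(
      "trace too short for the taper window: need at least %g s (%d samples), got %d",
      window_s, len, length(x)), "synq_contract_error")
  tapers <- dpss_tapers(len, nw, k)
  step <- max(1L, as.integer(round(len * (1 - overlap))))
  starts <- seq(1L, length(x) - len + 1L, by = step)
  nfreq <- len %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + len - 1L)]
    seg <- seg - mean(seg)
    spec <- mvfft(tapers * seg)[seq_len(nfreq), , drop = FALSE]
    acc <- acc + rowMeans(Mod(spec)^2) / fs
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when len is even)
  dbl <- rep(2, nfreq); dbl[1L] <- 1
  if (len %% 2L == 0L) dbl[nfreq] <- 1
  list(freq_hz = (seq_len(nfreq) - 1L) * fs / len, psd = psd * dbl,
       df_hz = fs / len)
}
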