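# Specification objects for the synthetic-data generators. Each constructor
# validates its invariants eagerly so generators can assume a valid spec.

#' Specification for a two-channel synaptic puncta field
#'
#' Describes the synthetic counterpart of a two-channel super-resolution
#' acquisition: `n_puncta_a` reference-channel puncta of which
#' `round(coloc_fraction * n_puncta_a)` are planted within
#' `max_center_offset_px` of a marker-channel punctum. Non-colocalized puncta
#' are kept at least `4 * punctum_radius_px` apart across channels so that the
#' planted truth is unambiguous under the disk-overlap colocalization rule.
#'
#' @param image_size height and width in pixels.
#' @param n_puncta_a,n_puncta_b puncta counts in the reference (A) and marker
#'   (B) channels.
#' @param coloc_fraction fraction of A puncta planted as colocalized pairs,
#'   in `[0, 1]`.
#' @param punctum_radius_px nominal punctum radius; rendering uses an
#'   isotropic Gaussian with `sigma = punctum_radius_px / 2` truncated at
#'   3 sigma. Default 6 px (~0.12 um at the ~0.02 um/px pitch typical of the
#'   targeted acquisitions); at the default detector settings a radius-4 spot
#'   would sit below the strict >25 px size gate, see the methods vignette.
#' @param peak_intensity spot peak intensity, arbitrary units.
#' @param background_sd Gaussian background noise SD, same units.
#' @param max_center_offset_px maximum center offset of a planted colocalized
#'   pair.
#' @return an object of class `puncta_field_spec`.
#' @export
puncta_field_spec <- function(image_size = c(1024L, 1024L),
                              n_puncta_a = 200, n_puncta_b = 200,
                              coloc_fraction = 0.3,
                              punctum_radius_px = 6,
                              peak_intensity = 1000,
                              background_sd = 20,
                              max_center_offset_px = 2) {
  if (length(image_size) != 2L) abort("`image_size` must be (height, width)",
                                      "synq_parameter_error")
  check_number(image_size[1], "image_size[height]", lower = 16, integer = TRUE)
  check_number(image_size[2], "image_size[width]", lower = 16, integer = TRUE)
  check_number(n_puncta_a, "n_puncta_a", lower = 0, integer = TRUE)
  check_number(n_puncta_b, "n_puncta_b", lower = 0, integer = TRUE)
  check_number(coloc_fraction, "coloc_fraction", lower = 0, upper = 1)
  check_number(punctum_radius_px, "punctum_radius_px", lower = 1)
  check_number(peak_intensity, "peak_intensity", lower = 0, strict_lower = TRUE)
  check_number(background_sd, "background_sd", lower = 0)
  check_number(max_center_offset_px, "max_center_offset_px", lower = 0)
  n_pairs <- round(coloc_fraction * n_puncta_a)
  if (n_pairs > n_puncta_b)
    abort("coloc_fraction * n_puncta_a exceeds n_puncta_b", "synq_parameter_error")
  structure(list(image_size = as.integer(image_size),
                 n_puncta_a = as.integer(n_puncta_a),
                 n_puncta_b = as.integer(n_puncta_b),
                 coloc_fraction = coloc_fraction,
                 punctum_radius_px = punctum_radius_px,
                 peak_intensity = peak_intensity,
                 background_sd = background_sd,
                 max_center_offset_px = max_center_offset_px,
                 n_pairs = as.integer(n_pairs)),
            class = "puncta_field_spec")
}

#' Specification for a depressing stimulus-train simulation
#'
#' Single-pool vesicle-depletion model of a high-frequency stimulus train.
#' With pool `N_1 = n0`, per-pulse release fraction `p`, replenishment
#' `r` vesicles/s and quantal size `q`, the noiseless amplitude obeys
#' `A_k = q * p * (N_ss + (n0 - N_ss) * (1 - p)^(k-1))` with steady state
#' `N_ss = r * dt / p`. The pool is deliberately not capped at `n0` during the
#' train: replenishment over a 5 s train is small relative to the resting
#' pool, so a cap would never engage at realistic parameters.
#'
#' @param n0 initial pool size, vesicles.
#' @param p_release per-pulse release fraction in `(0, 1]`.
#' @param r_replenish replenishment rate, vesicles/s.
#' @param q_amp quantal amplitude, pA per vesicle.
#' @param n_pulses pulses per sweep (default 100).
#' @param rate_hz stimulation rate (default 20 Hz).
#' @param noise_sd additive per-pulse amplitude noise SD, pA. The default is
#'   5% of the first-pulse amplitude at the default kinetics.
#' @param n_sweeps number of repeated sweeps.
#' @return an object of class `train_sim_spec`.
#' @export
train_sim_spec <- function(n0 = 1000, p_release = 0.3, r_replenish = 300,
                           q_amp = 4, n_pulses = 100, rate_hz = 20,
                           noise_sd = 0.05 * q_amp * p_release * n0,
                           n_sweeps = 15) {
  check_number(n0, "n0", lower = 0, strict_lower = TRUE)
  if (!is.numeric(p_release) || length(p_release) != 1L ||
      p_release <= 0 || p_release > 1)
    abort("`p_release` must lie in (0, 1]", "synq_parameter_error")
  check_number(r_replenish, "r_replenish", lower = 0)
  check_number(q_amp, "q_amp", lower = 0, strict_lower = TRUE)
  check_number(n_pulses, "n_pulses", lower = 1, integer = TRUE)
  check_number(rate_hz, "rate_hz", lower = 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(n_sweeps, "n_sweeps", lower = 1, integer = TRUE)
  structure(list(n0 = n0, p_release = p_release, r_replenish = r_replenish,
                 q_amp = q_amp, n_pulses = as.integer(n_pulses),
                 rate_hz = rate_hz, noise_sd = noise_sd,
                 n_sweeps = as.integer(n_sweeps)),
            class = "train_sim_spec")
}

#' Specification for a miniature-event trace simulation
#'
#' Homogeneous Poisson events, each a difference-of-exponentials transient
#' (peak-normalized), added negatively (inward current) to Gaussian noise.
#'
#' @param duration_s trace duration, s.
#' @param event_rate_hz Poisson event rate, Hz.
#' @param amp_mean,amp_sd event peak amplitude mean and SD, pA.
#' @param tau_rise_ms,tau_decay_ms kinetics, ms; decay must exceed rise.
#' @param noise_sd baseline Gaussian noise SD, pA.
#' @param fs_hz sampling rate (default 10 kHz, the acquisition standard for
#'   these recordings).
#' @return an object of class `mini_train_spec`.
#' @export
mini_train_spec <- function(duration_s = 120, event_rate_hz = 3,
                            amp_mean = 20, amp_sd = 2,
                            tau_rise_ms = 0.5, tau_decay_ms = 5,
                            noise_sd = 4, fs_hz = 10000) {
  check_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  check_number(event_rate_hz, "event_rate_hz", lower = 0)
  check_number(amp_mean, "amp_mean", lower = 0, strict_lower = TRUE)
  check_number(amp_sd, "amp_sd", lower = 0)
  check_number(tau_rise_ms, "tau_rise_ms", lower = 0, strict_lower = TRUE)
  check_number(tau_decay_ms, "tau_decay_ms", lower = 0, strict_lower = TRUE)
  if (tau_decay_ms <= tau_rise_ms)
    abort("`tau_decay_ms` must be greater than `tau_rise_ms`",
          "synq_parameter_error")
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(fs_hz, "fs_hz", lower = 100, strict_lower = TRUE)
  structure(list(duration_s = duration_s, event_rate_hz = event_rate_hz,
                 amp_mean = amp_mean, amp_sd = amp_sd,
                 tau_rise_ms = tau_rise_ms, tau_decay_ms = tau_decay_ms,
                 noise_sd = noise_sd, fs_hz = fs_hz),
            class = "mini_train_spec")
}

#' Specification for a wideband LFP trace simulation
#'
#' Sum of sinusoidal band components plus white Gaussian noise plus
#' negative-going extracellular spike templates at stated times, each scaled
#' to a stated multiple of the noise SD.
#'
#' @param duration_s trace duration, s.
#' @param fs_hz sampling rate (default 20 kHz, the full acquisition rate).
#' @param components list of `c(frequency_hz, amplitude)` pairs; all
#'   frequencies must be below `fs_hz / 2`.
#' @param spike_times_s spike insertion times, s (sorted internally).
#' @param spike_amp_sd_units spike peak magnitude in multiples of `noise_sd`;
#'   scalar or one value per spike. Spikes above 30 SD are flagged in the
#'   ground truth as falling in the artifact-exclusion range.
#' @param noise_sd white noise SD (must be positive when spikes are planted,
#'   since spike scale is defined in noise-SD units).
#' @return an object of class `lfp_spec`.
#' @export
lfp_spec <- function(duration_s = 10, fs_hz = 20000,
                     components = list(c(6, 20), c(40, 5)),
                     spike_times_s = numeric(), spike_amp_sd_units = 10,
                     noise_sd = 5) {
  check_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  check_number(fs_hz, "fs_hz", lower = 100, strict_lower = TRUE)
  if (!is.list(components)) abort("`components` must be a list of c(freq, amp)",
                                  "synq_parameter_error")
  for (cmp in components) {
    if (length(cmp) != 2L || !is.numeric(cmp))
      abort("each component must be c(frequency_hz, amplitude)",
            "synq_parameter_error")
    if (cmp[1] <= 0 || cmp[1] >= fs_hz / 2)
      abort(sprintf("component frequency %g Hz must lie in (0, fs/2)", cmp[1]),
            "synq_parameter_error")
  }
  check_number(noise_sd, "noise_sd", lower = 0)
  spike_times_s <- as.numeric(spike_times_s)
  if (length(spike_times_s)) {
    if (any(spike_times_s < 0) || any(spike_times_s > duration_s))
      abort("spike times must lie within [0, duration_s]", "synq_parameter_error")
    if (noise_sd <= 0)
      abort("`noise_sd` must be positive when spikes are planted",
            "synq_parameter_error")
    spike_amp_sd_units <- rep_len(spike_amp_sd_units, length(spike_times_s))
    if (any(spike_amp_sd_units <= 0))
      abort("`spike_amp_sd_units` must be positive", "synq_parameter_error")
    ord <- order(spike_times_s)         # keep each spike's amplitude paired
    spike_times_s <- spike_times_s[ord]
    spike_amp_sd_units <- spike_amp_sd_units[ord]
  }
  structure(list(duration_s = duration_s, fs_hz = fs_hz,
                 components = components, spike_times_s = spike_times_s,
                 spike_amp_sd_units = spike_amp_sd_units, noise_sd = noise_sd),
            class = "lfp_spec")
}

#' Specification for two-group scalar samples
#'
#' Groups are drawn from shifted/scaled Student-t distributions (the heavy
#' tails the BEST model assumes). For `nu > 2` the scale is chosen so the
#' distribution's standard deviation equals the stated SD (dividing the raw t
#' scale by `sqrt(nu / (nu - 2))`); for `nu <= 2` the SD does not exist and
#' the stated value is used as the raw scale parameter. `n_outliers` points of
#' group 1 are replaced by `mu1 + outlier_sd_offset * sd1`.
#'
#' @param n1,n2 sample sizes (each at least 2).
#' @param mu1,mu2 group means.
#' @param sd1,sd2 group SDs (scales, see above).
#' @param nu t normality parameter, positive.
#' @param n_outliers count of injected outliers (group 1).
#' @param outlier_sd_offset outlier location in multiples of `sd1`.
#' @return an object of class `group_sample_spec`.
#' @export
group_sample_spec <- function(n1 = 10, n2 = 10, mu1 = 0, mu2 = 0,
                              sd1 = 1, sd2 = 1, nu = 30,
                              n_outliers = 0, outlier_sd_offset = 10) {
  check_number(n1, "n1", lower = 2, integer = TRUE)
  check_number(n2, "n2", lower = 2, integer = TRUE)
  check_number(mu1, "mu1"); check_number(mu2, "mu2")
  check_number(sd1, "sd1", lower = 0, strict_lower = TRUE)
  check_number(sd2, "sd2", lower = 0, strict_lower = TRUE)
  check_number(nu, "nu", lower = 0, strict_lower = TRUE)
  check_number(n_outliers, "n_outliers", lower = 0, upper = n1, integer = TRUE)
  check_number(outlier_sd_offset, "outlier_sd_offset")
  structure(list(n1 = as.integer(n1), n2 = as.integer(n2), mu1 = mu1,
                 mu2 = mu2, sd1 = sd1, sd2 = sd2, nu = nu,
                 n_outliers = as.integer(n_outliers),
                 outlier_sd_offset = outlier_sd_offset),
            class = "group_sample_spec")
}

#' Specification for a random dendritic tree
#'
#' @param n_branches number of bifurcation nodes.
#' @param segment_length_um nominal segment length, um (the realized length is
#'   `total_length_um / round(total_length_um / segment_length_um)` so segment
#'   lengths sum exactly to the requested total).
#' @param branch_angle_deg angle between a parent direction and a new daughter
#'   branch.
#' @param total_length_um total dendritic length, um.
#' @return an object of class `tree_spec`.
#' @export
tree_spec <- function(n_branches = 5, segment_length_um = 10,
                      branch_angle_deg = 40, total_length_um = 600) {
  check_number(n_branches, "n_branches", lower = 0, integer = TRUE)
  check_number(segment_length_um, "segment_length_um", lower = 0,
               strict_lower = TRUE)
  check_number(branch_angle_deg, "branch_angle_deg", lower = 0, upper = 180)
  check_number(total_length_um, "total_length_um", lower = 0,
               strict_lower = TRUE)
  n_seg <- max(1L, as.integer(round(total_length_um / segment_length_um)))
  if (n_seg < 2L * n_branches + 1L)
    abort(sprintf(
      "impossible geometry: %d segments cannot host %d bifurcations (need >= %d)",
      n_seg, n_branches, 2L * n_branches + 1L), "synq_parameter_error")
  structure(list(n_branches = as.integer(n_branches),
                 segment_length_um = segment_length_um,
                 branch_angle_deg = branch_angle_deg,
                 total_length_um = total_length_um, n_segments = n_seg),
            class = "tree_spec")
}
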