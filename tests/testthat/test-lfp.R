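# Band power and extracellular spike detection.

test_that("band power concentrates in the band of a pure tone", {
  t6 <- simulate_lfp(lfp_spec(duration_s = 8, fs_hz = 2000,
                              components = list(c(6, 10)), noise_sd = 0.01), 1)
  bp6 <- band_power(t6$trace, t6$fs_hz)
  expect_gt(bp6$relative[["theta"]], 0.9)
  t40 <- simulate_lfp(lfp_spec(duration_s = 8, fs_hz = 2000,
                               components = list(c(40, 10)), noise_sd = 0.01), 1)
  bp40 <- band_power(t40$trace, t40$fs_hz)
  expect_identical(names(which.max(bp40$power)), "low_gamma")
  expect_gt(bp40$relative[["low_gamma"]], 0.9)
})

test_that("equal tones give equal band powers and the sum is the total", {
  tr <- simulate_lfp(lfp_spec(duration_s = 10, fs_hz = 2000,
                              components = list(c(6, 5), c(40, 5)),
                              noise_sd = 0.01), 2)
  bp <- band_power(tr$trace, tr$fs_hz)
  expect_lt(abs(bp$power[["theta"]] - bp$power[["low_gamma"]]) /
              bp$power[["low_gamma"]], 0.1)
  expect_identical(sum(bp$power), bp$total_power)
})

test_that("band power scales quadratically with amplitude", {
  tr <- simulate_lfp(lfp_spec(duration_s = 6, fs_hz = 2000, noise_sd = 1), 3)
  b1 <- band_power(tr$trace, 2000)
  b3 <- band_power(3 * tr$trace, 2000)
  expect_equal(b3$power, 9 * b1$power, tolerance = 1e-7)
  expect_equal(b3$total_power, 9 * b1$total_power, tolerance = 1e-7)
})

test_that("band power rejects too-short traces, naming the minimum", {
  err <- tryCatch(band_power(rnorm(1000), 2000), error = function(e) e)
  expect_s3_class(err, "synq_contract_error")
  expect_match(conditionMessage(err), "2 s")
})

test_that("spike detection finds planted spikes and excludes artifacts", {
  spike_t <- seq(0.5, 9.5, by = 0.25)
  spec <- lfp_spec(duration_s = 10, fs_hz = 20000,
                   components = list(c(6, 30)),
                   spike_times_s = spike_t, spike_amp_sd_units = 10,
                   noise_sd = 2)
  res <- simulate_lfp(spec, 4)
  det <- detect_spikes(res$trace, res$fs_hz)
  # recall >= 95% with timing error <= 0.2 ms
  matched <- vapply(spike_t, function(t0)
    any(abs(det$spike_times_s - t0) <= 2e-4), TRUE)
  expect_gte(mean(matched), 0.95)
  # false positives <= 5%
  is_fp <- vapply(det$spike_times_s, function(td)
    !any(abs(spike_t - td) <= 2e-4), TRUE)
  expect_lte(mean(is_fp), 0.05)
  # a -40 SD artifact is excluded by the 30 SD rule
  spec2 <- lfp_spec(duration_s = 4, fs_hz = 20000,
                    spike_times_s = c(1, 2, 3),
                    spike_amp_sd_units = c(10, 40, 10), noise_sd = 2)
  res2 <- simulate_lfp(spec2, 5)
  det2 <- detect_spikes(res2$trace, res2$fs_hz)
  expect_false(any(abs(det2$spike_times_s - 2) <= 5e-4))
  expect_true(any(abs(det2$excluded_times_s - 2) <= 5e-4))
  expect_true(any(abs(det2$spike_times_s - 1) <= 2e-4))
})

test_that("spike detection degenerate cases and snippet geometry", {
  # near-flat trace: no spikes
  tr <- rnorm(20000, 0, 1e-6)
  expect_identical(detect_spikes(tr, 20000)$n_spikes, 0L)
  # snippet spans -0.5..+3 ms: round(3.5 ms * fs) + 1 samples at any fs
  for (fs in c(10000, 20000)) {
    spec <- lfp_spec(duration_s = 2, fs_hz = fs, spike_times_s = c(0.7, 1.3),
                     spike_amp_sd_units = 12, noise_sd = 2)
    det <- detect_spikes(simulate_lfp(spec, 6)$trace, fs)
    expect_identical(ncol(det$waveforms), as.integer(round(0.0035 * fs)) + 1L)
    expect_identical(det$spike_times_s, sort(det$spike_times_s))
    # every retained peak magnitude within (5 SD, 30 SD]
    mags <- abs(apply(det$waveforms, 1, min, na.rm = TRUE))
    expect_true(all(mags > 5 * det$noise_sd & mags <= 30 * det$noise_sd))
  }
  # negative-range convention: positive-going deflections are not detected
  spec <- lfp_spec(duration_s = 2, fs_hz = 20000, spike_times_s = 1,
                   spike_amp_sd_units = 12, noise_sd = 2)
  flipped <- -simulate_lfp(spec, 7)$trace
  det_f <- detect_spikes(flipped, 20000)
  expect_false(any(abs(det_f$spike_times_s - 1) <= 2e-4))
  det_ff <- detect_spikes(-flipped, 20000)
  expect_true(any(abs(det_ff$spike_times_s - 1) <= 2e-4))
  expect_error(detect_spikes(rnorm(10000), 5000), class = "synq_parameter_error")
})
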