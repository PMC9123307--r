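# Synthetic-data generators: validation, planted truth, reproducibility.

test_that("spec constructors reject invalid parameters", {
  expect_error(train_sim_spec(p_release = 0), class = "synq_parameter_error")
  expect_error(train_sim_spec(p_release = 1.2), class = "synq_parameter_error")
  expect_error(train_sim_spec(n_pulses = 0), class = "synq_parameter_error")
  expect_error(mini_train_spec(tau_rise_ms = 5, tau_decay_ms = 5),
               class = "synq_parameter_error")
  expect_error(puncta_field_spec(coloc_fraction = 1.5),
               class = "synq_parameter_error")
  expect_error(lfp_spec(components = list(c(15000, 1)), fs_hz = 20000),
               class = "synq_parameter_error")
  expect_error(lfp_spec(spike_times_s = 99, duration_s = 10),
               class = "synq_parameter_error")
  expect_error(group_sample_spec(n1 = 1), class = "synq_parameter_error")
  expect_error(tree_spec(n_branches = 40, total_length_um = 100,
                         segment_length_um = 10),
               class = "synq_parameter_error")
})

test_that("generators are bit-reproducible for a fixed seed", {
  spec_p <- puncta_field_spec(image_size = c(96, 96), n_puncta_a = 2,
                              n_puncta_b = 2, coloc_fraction = 0.5)
  expect_identical(gen_puncta_image_pair(spec_p, 7),
                   gen_puncta_image_pair(spec_p, 7))
  expect_identical(simulate_train(train_sim_spec(), 7),
                   simulate_train(train_sim_spec(), 7))
  spec_m <- mini_train_spec(duration_s = 2)
  expect_identical(simulate_mini_trace(spec_m, 7), simulate_mini_trace(spec_m, 7))
  spec_l <- lfp_spec(duration_s = 2, spike_times_s = c(0.5, 1.2))
  expect_identical(simulate_lfp(spec_l, 7), simulate_lfp(spec_l, 7))
  expect_identical(gen_group_samples(group_sample_spec(), 7),
                   gen_group_samples(group_sample_spec(), 7))
  expect_identical(gen_tree(tree_spec(), 7), gen_tree(tree_spec(), 7))
})

test_that("puncta truth pair count follows the planted fraction", {
  base <- list(image_size = c(1024, 1024), punctum_radius_px = 6)
  cases <- list(list(frac = 0, n_a = 50, pairs = 0),
                list(frac = 1, n_a = 50, pairs = 50),
                list(frac = 0.3, n_a = 200, pairs = 60))
  for (cs in cases) {
    spec <- puncta_field_spec(image_size = base$image_size,
                              n_puncta_a = cs$n_a, n_puncta_b = cs$n_a,
                              coloc_fraction = cs$frac)
    res <- gen_puncta_image_pair(spec, 11)
    expect_identical(nrow(res$truth$pairs), as.integer(cs$pairs))
    expect_identical(sum(res$truth$centers_a$colocalized), as.integer(cs$pairs))
    # all planted centers inside image bounds
    expect_true(all(res$truth$centers_a$row >= 0 &
                      res$truth$centers_a$row <= spec$image_size[1] - 1))
    expect_true(all(res$truth$centers_b$col >= 0 &
                      res$truth$centers_b$col <= spec$image_size[2] - 1))
  }
})

test_that("non-colocalized puncta respect the 4-radius separation", {
  spec <- puncta_field_spec(image_size = c(512, 512), n_puncta_a = 20,
                            n_puncta_b = 20, coloc_fraction = 0.25)
  res <- gen_puncta_image_pair(spec, 3)
  ctr <- rbind(as.matrix(res$truth$centers_a[, 1:2]),
               as.matrix(res$truth$centers_b[, 1:2]))
  d <- as.matrix(dist(ctr))
  diag(d) <- Inf
  # planted pairs are the only permitted close approaches
  n_pairs <- nrow(res$truth$pairs)
  for (i in seq_len(n_pairs)) d[i, 20 + i] <- d[20 + i, i] <- Inf
  expect_true(min(d) >= 4 * spec$punctum_radius_px)
  # pair offsets bounded as specified
  for (i in seq_len(n_pairs)) {
    off <- sqrt(sum((res$truth$centers_a[i, 1:2] -
                       res$truth$centers_b[i, 1:2])^2))
    expect_lte(off, spec$max_center_offset_px)
  }
})

test_that("impossible puncta placement raises a placement error", {
  spec <- puncta_field_spec(image_size = c(64, 64), n_puncta_a = 40,
                            n_puncta_b = 40, coloc_fraction = 0)
  expect_error(gen_puncta_image_pair(spec, 1), class = "synq_placement_error")
})

test_that("noiseless trains match the literal recursion oracle exactly", {
  grid <- expand.grid(n0 = c(500, 1000), p = c(0.2, 0.35, 1),
                      r = c(0, 120, 300))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    spec <- train_sim_spec(n0 = g$n0, p_release = g$p, r_replenish = g$r,
                           noise_sd = 0, n_sweeps = 2)
    rec <- simulate_train(spec, 5)
    oracle <- oracle_train_recursion(g$n0, g$p, g$r, 4, 100, 20)
    expect_equal(rec$amplitudes[1, ], oracle, tolerance = 1e-12)
    expect_equal(rec$amplitudes[2, ], oracle, tolerance = 1e-12)
    # closed form holds to near machine precision for all pulses
    expect_equal(attr(rec, "truth")$amplitudes, oracle, tolerance = 1e-10)
  }
})

test_that("train limit cases behave as forced by the model", {
  # p = 1, no replenishment: everything released on pulse 1
  rec <- simulate_train(train_sim_spec(n0 = 100, p_release = 1,
                                       r_replenish = 0, noise_sd = 0,
                                       n_sweeps = 1), 1)
  expect_equal(rec$amplitudes[1, 1], 4 * 100)
  expect_equal(unname(rec$amplitudes[1, -1]), rep(0, 99))
  # steady state from pulse 1 when r * dt = p * n0
  rec2 <- simulate_train(train_sim_spec(n0 = 100, p_release = 0.25,
                                        r_replenish = 0.25 * 100 * 20,
                                        noise_sd = 0, n_sweeps = 1), 1)
  expect_equal(diff(range(rec2$amplitudes[1, ])), 0)
})

test_that("mini traces honour their planted truth", {
  # zero rate: pure noise, empty truth
  res0 <- simulate_mini_trace(mini_train_spec(duration_s = 2,
                                              event_rate_hz = 0), 1)
  expect_identical(nrow(res0$truth), 0L)
  expect_equal(sd(res0$trace), 4, tolerance = 0.1)
  # amp_sd = 0: every truth amplitude equals amp_mean
  res1 <- simulate_mini_trace(mini_train_spec(duration_s = 10, amp_sd = 0), 2)
  expect_true(all(res1$truth$amplitude_pa == 20))
  expect_true(all(res1$truth$time_s >= 0 & res1$truth$time_s <= 10))
})

test_that("mini event counts follow the Poisson law", {
  # mean truth count over 100 seeds within the 95% interval of the mean
  spec <- mini_train_spec(duration_s = 120, event_rate_hz = 3, fs_hz = 500)
  counts <- vapply(1:100, function(s)
    nrow(simulate_mini_trace(spec, s)$truth), 0L)
  expect_lt(abs(mean(counts) - 360), 1.96 * sqrt(360 / 100))
  # chi-square goodness of fit against Poisson(6) over 1000 seeds
  spec2 <- mini_train_spec(duration_s = 2, event_rate_hz = 3, fs_hz = 500)
  k <- vapply(1:1000, function(s) nrow(simulate_mini_trace(spec2, s)$truth), 0L)
  breaks <- c(-Inf, 2:9, Inf)
  obs <- table(cut(k, breaks))
  pr <- diff(ppois(c(-Inf, 2:9, Inf), 6))
  expect_gt(suppressWarnings(chisq.test(as.integer(obs), p = pr)$p.value),
            0.01)
})

test_that("lfp traces carry their components and spike truth", {
  # pure tone, no noise: periodogram peak exactly at the component
  res <- simulate_lfp(lfp_spec(duration_s = 4, fs_hz = 1000,
                               components = list(c(6, 2)), noise_sd = 0), 1)
  sp <- Mod(fft(res$trace))[2:2000]
  expect_equal((which.max(sp)) / 4, 6)  # df = 1/4 Hz
  # spike truth: sorted, exclusion flag above 30 SD
  res2 <- simulate_lfp(lfp_spec(duration_s = 2, fs_hz = 20000,
                                spike_times_s = c(1.5, 0.3, 0.9),
                                spike_amp_sd_units = c(10, 40, 12),
                                noise_sd = 2), 2)
  expect_identical(res2$truth$time_s, sort(res2$truth$time_s))
  expect_identical(res2$truth$above_exclusion,
                   res2$truth$amp_sd_units > 30)
  expect_identical(sum(res2$truth$above_exclusion), 1L)
})

test_that("group samples match their stated moments and outlier truth", {
  spec <- group_sample_spec(n1 = 10000, n2 = 10, sd1 = 2.5, nu = 30)
  g <- gen_group_samples(spec, 4)
  expect_lt(abs(sd(g$group1) - 2.5) / 2.5, 0.03)
  g2 <- gen_group_samples(group_sample_spec(n_outliers = 2), 5)
  expect_identical(length(g2$truth$outlier_idx), 2L)
  expect_true(all(g2$group1[g2$truth$outlier_idx] == 10))
})

test_that("generated trees satisfy their geometric contract", {
  # no branches: a single unbranched path
  t0 <- gen_tree(tree_spec(n_branches = 0, total_length_um = 100), 1)
  expect_identical(max(table(t0$parent[t0$parent > 0])), 1L)
  for (seed in 1:5) {
    spec <- tree_spec(n_branches = 7, total_length_um = 300)
    tr <- gen_tree(spec, seed)
    pidx <- match(tr$parent, tr$id)
    seg_len <- sqrt((tr$x - tr$x[pidx])^2 + (tr$y - tr$y[pidx])^2 +
                      (tr$z - tr$z[pidx])^2)[tr$parent > 0]
    expect_lt(abs(sum(seg_len) - 300) / 300, 0.01)
    # branch count = nodes with two children
    kids <- table(tr$parent[tr$parent > 0])
    expect_identical(sum(kids >= 2), 7L)
    expect_true(all(kids <= 2))
    # connected, acyclic, parents precede children (validated by the reader
    # contract used in sholl)
    expect_silent(sholl(tr, 6, 60))
  }
})
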