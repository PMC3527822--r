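# Generator: state sequence, up/down phases, spike trains, waveform
# templates, LFP and the on-disk dataset contract.

test_that("epoch durations follow the truncated exponential with the configured mean", {
  cfg <- sim_config(duration_s = 50000, n_channels = 1, seed = 11,
                    state_mean_durations = c(synchronized = 100,
                                             desynchronized = 100),
                    class_params = list(dPC = class_param(0, 1, 1)))
  st <- generate_state_sequence(cfg)
  d <- st$epochs$end_s - st$epochs$start_s
  d <- d[-length(d)]                      # last epoch clipped by the window
  expect_true(all(d >= 10))
  expect_lt(abs(mean(d) - 100), 3 * sd(d) / sqrt(length(d)))
  # left-truncated exponential: (d - 10) is exponential with mean 90
  ks <- suppressWarnings(stats::ks.test(d - 10, stats::pexp, 1 / 90))
  expect_gt(ks$p.value, 0.01)
})

test_that("epoch means match the anesthetized preset and partition the recording", {
  cfg <- sim_config(duration_s = 50000, n_channels = 1, seed = 4,
                    class_params = list(dPC = class_param(0, 1, 1)))
  st <- generate_state_sequence(cfg)
  e <- st$epochs
  expect_equal(e$start_s[1], 0)
  expect_equal(e$end_s[nrow(e)], 50000)
  expect_true(all(abs(e$start_s[-1] - e$end_s[-nrow(e)]) < 1e-9))
  e <- e[-nrow(e), ]                      # last epoch clipped by the window
  d <- e$end_s - e$start_s
  expect_true(all(d > 0))
  targets <- c(synchronized = 167, desynchronized = 165)
  for (nm in names(targets)) {
    ds <- d[e$state == nm]
    expect_lt(abs(mean(ds) - targets[[nm]]), 3 * sd(ds) / sqrt(length(ds)))
  }
})

test_that("an infinite desynchronized mean gives a single synchronized state", {
  cfg <- sim_config(duration_s = 500, n_channels = 1, seed = 1,
                    state_mean_durations = c(synchronized = 100,
                                             desynchronized = Inf),
                    class_params = list(dPC = class_param(0, 1, 1)))
  st <- generate_state_sequence(cfg)
  expect_true(all(st$bin_labels == "synchronized"))
  expect_equal(nrow(st$epochs), 1)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(duration_s = -5), "duration")
  expect_error(sim_config(state_mean_durations = c(synchronized = 0,
                                                   desynchronized = 100)),
               "mean durations")
  expect_error(sim_config(class_params = list(
    dPC = class_param(2, 3, 1, burst_prob = 1.5))), "burst_prob")
  expect_error(sim_config(class_params = list(
    dPC = class_param(2, 3, 1, depth_range_um = c(100, 1700)))), "depth_range")
  cfg <- sim_config(state_mean_durations = c(synchronized = 5,
                                             desynchronized = 100),
                    class_params = list(dPC = class_param(0, 1, 1)),
                    n_channels = 1)
  expect_error(generate_state_sequence(cfg), "truncation")
})

test_that("up/down phase time fractions follow the configured duration means", {
  for (mu in list(c(up = 0.5, down = 0.5), c(up = 0.3, down = 0.7))) {
    cfg <- one_class_cfg(0, duration_s = 1500, seed = 7, updown = mu,
                         state_means = c(synchronized = 200,
                                         desynchronized = Inf))
    st <- generate_state_sequence(cfg)
    ud <- generate_updown_phases(st, cfg)
    expect_equal(length(ud), 1500 * 100)
    frac <- mean(ud == "up")
    expect_lt(abs(frac - mu[["up"]] / sum(mu)), 0.05)
  }
})

test_that("up/down labels are n/a exactly on desynchronized bins", {
  cfg <- one_class_cfg(0, duration_s = 1000, seed = 3)
  st <- generate_state_sequence(cfg)
  ud <- generate_updown_phases(st, cfg)
  parent <- rep(st$bin_labels, each = 100)
  expect_identical(ud == "na", parent == "desynchronized")

  # desynchronized-only sequence: everything n/a
  cfg2 <- one_class_cfg(0, duration_s = 300, seed = 3,
                        state_means = c(synchronized = Inf,
                                        desynchronized = 100))
  ud2 <- generate_updown_phases(generate_state_sequence(cfg2), cfg2)
  expect_true(all(ud2 == "na"))
})

test_that("spike trains realize the design rates in both states", {
  cfg <- one_class_cfg(1, rate = 3, gain = 1, duration_s = 10000, seed = 21)
  sim <- simulate_recording(cfg, lfp = FALSE, waveforms = FALSE)
  seg <- truth_segmentation(sim$states)
  r <- rate_by_state_spontaneous(spikes_of(sim, "u001"), seg)
  se_s <- sqrt(3 / (sum(seg$bin_labels == "synchronized")))
  se_d <- sqrt(3 / (sum(seg$bin_labels == "desynchronized")))
  expect_lt(abs(r$fr_s - 3), 3 * se_s)
  expect_lt(abs(r$fr_d - 3), 3 * se_d)
})

test_that("gain 0 silences the desynchronized state", {
  cfg <- one_class_cfg(2, rate = 5, gain = 0, duration_s = 2000, seed = 5)
  sim <- simulate_recording(cfg, lfp = FALSE, waveforms = FALSE)
  seg <- truth_segmentation(sim$states)
  de <- seg$epochs[seg$epochs$state == "desynchronized", ]
  in_de <- vapply(sim$units$spikes$time_s, function(t)
    any(t >= de$start_s & t < de$end_s), logical(1))
  expect_false(any(in_de))
})

test_that("doublet bursts add burst_prob extra spikes per seed spike", {
  cfg <- one_class_cfg(1, rate = 5, gain = 1, burst_prob = 0.2,
                       duration_s = 10000, seed = 31,
                       updown = c(up = 0.5, down = 0))
  sim <- simulate_recording(cfg, lfp = FALSE, waveforms = FALSE)
  n <- nrow(sim$units$spikes)
  expected <- 5 * 1.2 * 10000
  expect_lt(abs(n - expected), 3 * sqrt(expected * 1.2))
  expect_equal(sim$units$units$true_fr_s, 6)
})

test_that("long-run class rates match design rates for every preset class", {
  cfg <- sim_config(duration_s = 3000, n_channels = 1, seed = 41)
  sim <- simulate_recording(cfg, lfp = FALSE, waveforms = FALSE)
  seg <- truth_segmentation(sim$states)
  ns <- sum(seg$bin_labels == "synchronized")
  for (i in seq_len(nrow(sim$units$units))) {
    u <- sim$units$units[i, ]
    r <- rate_by_state_spontaneous(spikes_of(sim, u$unit_id), seg)
    # 4 sigma: 62 simultaneous per-unit checks
    expect_lt(abs(r$fr_s - u$true_fr_s), 4 * sqrt(u$true_fr_s / ns) + 1e-9)
  }
})

test_that("waveform templates realize the requested features", {
  grid <- expand.grid(ttp = c(0.35, 0.5, 0.7), hw = c(0.20, 0.25),
                      asym = c(-0.3, 0, 0.4, 1))
  grid <- grid[grid$ttp >= 1.3 * grid$hw, ]
  fs <- 20000
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    w <- waveform_template(g$ttp, g$hw, g$asym, fs = fs)
    f <- extract_waveform_features(w, fs)
    expect_lt(abs(f$trough_to_peak_ms - g$ttp), 1000 / fs)
    expect_lt(abs(f$half_width_ms - g$hw), 1000 / fs)
    expect_lt(abs(f$asymmetry - g$asym), 0.02)
  }
  expect_error(waveform_template(0.2, 0.4, 0), "unrealizable")
  expect_error(waveform_template(0.5, 0.25, -1), "asymmetry")
})

test_that("the soma channel carries the maximum amplitude", {
  cfg <- sim_config(duration_s = 60, seed = 2, waveform_noise_sd = 0,
                    class_params = list(dPC = class_param(
                      1, 3, 1, depth_range_um = c(900, 900))))
  sim <- simulate_recording(cfg, lfp = FALSE)
  wf <- sim$units$waveforms[["u001"]]
  amp <- apply(wf, 1, function(r) max(r) - min(r))
  expect_equal(channel_depths(cfg)[which.max(amp)], 900)
})

test_that("LFP band power separates the states when the oscillation dominates", {
  cfg <- one_class_cfg(0, duration_s = 3600, seed = 13)   # amp ratio 10
  sim <- simulate_recording(cfg, waveforms = FALSE)
  ps <- compute_low_freq_power(sim$recording)
  lp <- ps$log_power
  sync <- sim$states$bin_labels == "synchronized"
  expect_gt(quantile(lp[sync], 0.01), quantile(lp[!sync], 0.99))
})

test_that("a zero-amplitude oscillation leaves the states indistinguishable", {
  cfg <- one_class_cfg(0, duration_s = 1200, seed = 17,
                       lfp_params = list(sync_osc_amp = 0, noise_amp = 20))
  sim <- simulate_recording(cfg, waveforms = FALSE)
  ps <- compute_low_freq_power(sim$recording)
  sync <- sim$states$bin_labels == "synchronized"
  p <- t.test(ps$log_power[sync], ps$log_power[!sync])$p.value
  expect_gt(p, 0.001)
})

test_that("generate_dataset is bit-reproducible and bookkeeps units", {
  cfg <- sim_config(duration_s = 60, n_channels = 4, lfp_fs = 500, seed = 9,
                    class_params = lapply(
                      c(sPC = 1, dPC = 1, sFS = 1, dFS = 1),
                      function(n) class_param(10, 3, 1,
                                              depth_range_um = c(100, 1100))))
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  unlink(c(d1, d2), recursive = TRUE)
  r1 <- generate_dataset(cfg, d1)
  r2 <- generate_dataset(cfg, d2)
  expect_identical(r1$manifest$checksums, r2$manifest$checksums)
  expect_equal(nrow(r1$sim$units$units), 40)
  expect_equal(as.vector(table(r1$sim$units$units$class)[c("sPC", "dPC")]),
               c(10L, 10L))
  cfg2 <- cfg; cfg2$seed <- 10L
  d3 <- file.path(tempdir(), "ds3"); unlink(d3, recursive = TRUE)
  r3 <- generate_dataset(cfg2, d3)
  expect_false(identical(r1$sim$states$epochs, r3$sim$states$epochs))
  unlink(c(d1, d2, d3), recursive = TRUE)
})
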