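# State-dependent firing statistics.

test_that("spontaneous rate counting is exact on constructed trains", {
  seg <- truth_segmentation(structure(list(
    bin_labels = rep(c("synchronized", "desynchronized"), each = 10)),
    class = "cort_states"))
  spikes <- seq(0.5, 9.5, by = 1)          # 10 spikes in the 10 sync bins
  r <- rate_by_state_spontaneous(spikes, seg)
  expect_equal(r$fr_s, 1.0)
  expect_equal(r$fr_d, 0.0)
  expect_true("low_bins" %in% r$flags)

  r0 <- rate_by_state_spontaneous(numeric(0), seg)
  expect_equal(r0$fr_s, 0)
  expect_equal(r0$fr_d, 0)
  expect_true(is.na(modulation_index(r0$fr_d, r0$fr_s)))
})

test_that("evoked rate counting is exact and skips ineffective events", {
  w <- data.frame(stim_time = c(100, 200), pre_start = c(98, 198),
                  pre_end = c(100, 200), post_start = c(101, 201),
                  post_end = c(103, 203), effective = c(TRUE, FALSE))
  class(w) <- c("cort_stim_windows", "data.frame")
  spikes <- c(98.1, 98.5, 99.2, 99.9, 101.5, 198.5, 202.0)
  r <- rate_by_state_evoked(spikes, w, min_events = 1)
  expect_equal(r$fr_s, 2.0)                # 4 pre spikes / 2 s, one event
  expect_equal(r$fr_d, 0.5)
  all_off <- w; all_off$effective <- FALSE
  r2 <- rate_by_state_evoked(spikes, all_off)
  expect_false(r2$available)
  expect_true("no_effective_events" %in% r2$flags)
})

test_that("modulation index algebra: values, bounds, sign, invariances", {
  expect_equal(modulation_index(6, 2), 0.5)
  expect_equal(modulation_index(5, 0), 1.0)
  expect_equal(modulation_index(0, 5), -1.0)
  expect_true(is.na(modulation_index(0, 0)))
  expect_error(modulation_index(-1, 2), "non-negative")
  set.seed(6)
  for (i in 1:200) {
    fr <- runif(2, 0, 50)
    mi <- modulation_index(fr[1], fr[2])
    expect_true(mi >= -1 && mi <= 1)
    expect_equal(sign(mi), sign(fr[1] - fr[2]))
    expect_equal(modulation_index(3.7 * fr[1], 3.7 * fr[2]), mi)
    if (fr[1] > 0) expect_equal(modulation_index(fr[1], fr[1]), 0)
  }
})

test_that("per-cell significance detects strong suppression and flags zero variance", {
  hits <- vapply(1:10, function(i) {
    cfg <- one_class_cfg(1, rate = 3, gain = 0.2, duration_s = 1200, seed = 100 + i,
                         state_means = c(synchronized = 60, desynchronized = 60))
    sim <- simulate_recording(cfg, lfp = FALSE, waveforms = FALSE)
    seg <- truth_segmentation(sim$states)
    s <- per_cell_significance(rate_by_state_spontaneous(spikes_of(sim, "u001"), seg))
    s$sig_class == "suppressed"
  }, logical(1))
  expect_true(all(hits))

  seg <- truth_segmentation(structure(list(
    bin_labels = rep(c("synchronized", "desynchronized"), each = 40)),
    class = "cort_states"))
  const <- seq(0.5, 79.5, by = 1)          # exactly one spike every bin
  s <- per_cell_significance(rate_by_state_spontaneous(const, seg))
  expect_equal(s$sig_class, "ns")
  expect_true("zero_variance" %in% s$flags)
  expect_true(is.na(s$p_value))
})

test_that("signed-rank p-values match exhaustive sign-pattern enumeration", {
  enum_p <- function(x) {
    # two-sided exact signed-rank p by enumerating all 2^n sign patterns
    n <- length(x)
    rk <- rank(abs(x))
    v_obs <- sum(rk[x > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- signs %*% rk
    mu <- n * (n + 1) / 4
    mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-9)
  }
  expect_equal(population_signed_rank(c(0.1, 0.2, 0.3, 0.4, 0.5))$p_value, 0.0625)
  set.seed(7)
  for (i in 1:5) {
    x <- round(runif(8, -1, 1), 3)
    expect_equal(population_signed_rank(x)$p_value, enum_p(x), tolerance = 1e-9)
  }
  expect_equal(population_signed_rank(rep(0, 6))$p_value, 1)
  sym <- c(-0.4, 0.4, -0.2, 0.2, -0.1, 0.1)
  expect_gt(population_signed_rank(sym)$p_value, 0.99)
})

test_that("burst fractions of Poisson trains match the closed form", {
  cfg <- one_class_cfg(1, rate = 5, duration_s = 4000, seed = 83,
                       updown = c(up = 0.5, down = 0),
                       state_means = c(synchronized = 200,
                                       desynchronized = Inf))
  sim <- simulate_recording(cfg, lfp = FALSE, waveforms = FALSE)
  seg <- truth_segmentation(sim$states)
  bf <- burst_fraction(spikes_of(sim, "u001"), seg, window_ms = c(10, 15, 20, 25))
  for (i in seq_len(nrow(bf))) {
    w <- bf$window_ms[i]
    expected <- 1 - exp(-5 * w / 1000)
    se <- sqrt(expected * (1 - expected) / bf$n_isi_sync[i])
    expect_lt(abs(bf$frac_sync[i] - expected), 4 * se)
  }
})

test_that("burst fraction is 0 for regular trains and respects epoch boundaries", {
  seg <- truth_segmentation(structure(list(
    bin_labels = rep(c("synchronized", "desynchronized"), each = 30)),
    class = "cort_states"))
  regular <- seq(0.05, 29.95, by = 0.1)
  bf <- burst_fraction(regular, seg)
  expect_equal(bf$frac_sync, 0)
  expect_true(is.na(bf$frac_desync))       # < 2 spikes there
  # an ISI spanning the state boundary must be discarded
  spikes <- c(29.99, 30.01, 30.02, 40.0, 40.005)
  bf2 <- burst_fraction(spikes, seg)
  expect_equal(bf2$n_isi_sync, 0)
  expect_equal(bf2$n_isi_desync, 3)
})

test_that("doublet trains match the generator's analytic burst fraction", {
  p <- 0.3
  cfg <- one_class_cfg(1, rate = 4, burst_prob = p, duration_s = 4000, seed = 89,
                       updown = c(up = 0.5, down = 0),
                       state_means = c(synchronized = 200,
                                       desynchronized = Inf))
  sim <- simulate_recording(cfg, lfp = FALSE, waveforms = FALSE)
  seg <- truth_segmentation(sim$states)
  bf <- burst_fraction(spikes_of(sim, "u001"), seg)
  expected <- analytic_burst_fraction(4, p, state = "synchronized",
                                      up_mean_s = 0.5, down_mean_s = 0)
  se <- sqrt(expected * (1 - expected) / bf$n_isi_sync)
  expect_lt(abs(bf$frac_sync - expected), 4 * se)
})

test_that("solve_burst_prob inverts the analytic fraction and clamps at the floor", {
  target <- analytic_burst_fraction(4, 0.25, state = "synchronized")
  p <- solve_burst_prob(target, baseline_rate_hz = 4, state = "synchronized")
  expect_equal(p, 0.25, tolerance = 1e-6)
  floor_frac <- analytic_burst_fraction(4, 0, state = "synchronized")
  expect_warning(p0 <- solve_burst_prob(floor_frac * 0.9, baseline_rate_hz = 4,
                                        state = "synchronized"),
                 "Poisson floor")
  expect_equal(p0, 0)
})

test_that("Kruskal-Wallis p-values are uniform under the null", {
  set.seed(8)
  ps <- replicate(300, {
    b <- data.frame(class = rep(c("sPC", "dPC"), each = 15),
                    frac_sync = runif(30), frac_desync = runif(30))
    burst_state_comparison(b)$kruskal_p
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("rank-sum post-hoc detects a shifted class and is 1 for identical groups", {
  set.seed(9)
  hits <- replicate(40, {
    b <- data.frame(class = "dPC", frac_sync = runif(30, 0.1, 0.2),
                    frac_desync = runif(30, 0.1, 0.2) - 0.05)
    burst_state_comparison(b)$class_tests$p_value < 0.05
  })
  expect_gte(mean(hits), 0.8)
  same <- data.frame(class = "dPC", frac_sync = rep(0.15, 8),
                     frac_desync = rep(0.15, 8))
  expect_equal(burst_state_comparison(same)$class_tests$p_value, 1)
})

test_that("the semi-log regression is exact on constructed data and null-calibrated", {
  fr <- c(0.5, 1, 2, 4, 8, 16)
  mi <- 0.2 * log10(fr)
  co <- rate_modulation_correlation(fr, mi)
  expect_equal(co$r, 1.0, tolerance = 1e-9)
  expect_equal(co$slope, 0.2, tolerance = 1e-9)
  expect_equal(co$intercept, 0, tolerance = 1e-9)

  set.seed(10)
  rs <- replicate(300, {
    fr <- 10^runif(30, -1, 1)
    rate_modulation_correlation(fr, runif(30, -0.5, 0.5))$r
  })
  expect_lt(abs(mean(rs)), 0.05)
  # null |r| quantile for n = 30: t-based cutoff at alpha = 0.05
  cutoff <- sqrt(qt(0.975, 28)^2 / (qt(0.975, 28)^2 + 28))
  expect_lt(abs(quantile(abs(rs), 0.95) - cutoff), 0.08)
  # zero-rate units are excluded, degenerate input undefined
  expect_true(is.na(rate_modulation_correlation(rep(2, 6), rep(0.1, 6))$r))
  expect_equal(rate_modulation_correlation(c(0, 0, 1, 2, 3, 4),
                                           c(0.9, 0.9, 0.1, 0.2, 0.3, 0.4))$n, 4)
})

test_that("multiunit modulation resolves the laminar gain pattern", {
  cfg <- sim_config(duration_s = 1500, n_channels = 1, seed = 91,
                    class_params = list(
                      sPC = class_param(8, 2, 0.3, depth_range_um = c(100, 450)),
                      dPC = class_param(8, 3, 1.6, depth_range_um = c(850, 1050))))
  sim <- simulate_recording(cfg, lfp = FALSE, waveforms = FALSE)
  seg <- truth_segmentation(sim$states)
  depths <- stats::setNames(sim$units$units$depth_um, sim$units$units$unit_id)
  m <- mua_modulation(sim$units$spikes, depths, seg)
  expect_lt(m$mi[m$window == "superficial"], 0)
  expect_gt(m$mi[m$window == "deep"], 0)
  # empty windows are dropped
  m2 <- mua_modulation(sim$units$spikes, depths, seg,
                       depth_windows = list(mid = c(600, 700)))
  expect_equal(nrow(m2), 0)
  # across-recording test degenerates gracefully at n = 1
  expect_true(is.na(mua_modulation_test(0.3)$p_value))
  expect_lt(mua_modulation_test(rep(c(-0.3, -0.25), 10))$p_value, 0.05)
})

test_that("population summary tabulates classes, ratios and count identities", {
  results <- data.frame(unit_id = sprintf("u%03d", 1:20),
                        fr_s = runif(20, 1, 5), fr_d = runif(20, 1, 5),
                        mi = runif(20, -0.5, 0.5),
                        p_value = runif(20),
                        sig_class = rep(c("enhanced", "suppressed", "ns", "ns"), 5))
  labels <- data.frame(unit_id = sprintf("u%03d", 1:20),
                       putative_class = rep(c("PC", "FS"), 10),
                       layer = rep(c("superficial", "deep"), each = 10),
                       included = TRUE)
  s <- summarize_population(results, labels)
  tab <- s$class_table
  expect_equal(tab$class, c("sPC", "dPC", "sFS", "dFS"))
  expect_equal(sum(tab$n), 20)
  for (i in seq_len(nrow(tab))) {
    expect_lte(tab$n_enhanced[i] + tab$n_suppressed[i], tab$n[i])
    expect_match(tab$ratio[i], "^[0-9]+:[0-9]+$")
  }
  # an empty class yields an empty ratio row
  s2 <- summarize_population(results[1:2, ], labels[1:2, ])
  expect_equal(s2$class_table$ratio[s2$class_table$n == 0][1], "")
})

test_that("gain recovery: configured class gains match (1+MI)/(1-MI)", {
  cfg <- sim_config(duration_s = 2500, n_channels = 1, seed = 97,
                    class_params = list(
                      sPC = class_param(6, 2.0, 0.4, depth_range_um = c(100, 500)),
                      dPC = class_param(6, 4.0, 1.5, depth_range_um = c(800, 1100))))
  sim <- simulate_recording(cfg, lfp = FALSE, waveforms = FALSE)
  seg <- truth_segmentation(sim$states)
  for (cl in c("sPC", "dPC")) {
    ids <- sim$units$units$unit_id[sim$units$units$class == cl]
    mis <- vapply(ids, function(u) {
      r <- rate_by_state_spontaneous(spikes_of(sim, u), seg)
      modulation_index(r$fr_d, r$fr_s)
    }, numeric(1))
    g_hat <- (1 + mis) / (1 - mis)
    g_cfg <- cfg$class_params[[cl]]$desync_gain
    expect_lt(abs(mean(g_hat) - g_cfg),
              3 * sd(g_hat) / sqrt(length(g_hat)) + 0.05)
  }
})
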