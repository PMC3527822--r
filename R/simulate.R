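# Synthetic laminar recording generator.  Produces ground-truth-annotated
# two-state recordings: an alternating synchronized/desynchronized state
# sequence, up/down phases inside synchronized epochs, inhomogeneous
# Poisson spike trains with doublet bursts for four cell classes, biphasic
# spike waveform templates on a laminar probe, and an LFP whose 0-7 Hz
# power separates the two states.

# Draw alternating exponential durations until their sum covers `len`.
draw_alternating <- function(len, m1, m2) {
  durs <- numeric(0)
  total <- 0
  step <- 0.5 * (m1 + m2)
  while (total < len) {
    n <- max(16L, ceiling((len - total) / step) + 8L)
    d <- as.vector(rbind(rexp(n, 1 / m1), rexp(n, 1 / m2)))
    durs <- c(durs, d)
    total <- total + sum(d)
  }
  durs
}

#' Generate an alternating cortical state sequence
#'
#' Epoch durations are drawn from left-truncated exponential
#' distributions: duration = `min_epoch_trunc_s + Exp(mean -
#' min_epoch_trunc_s)`, so that no epoch is shorter than the truncation
#' point and the realized mean equals the configured per-state mean
#' (the configured means must exceed the truncation point).  The first
#' epoch's state is drawn with probability proportional to the state
#' means.  Labels are discretized at 1-s bins by bin midpoint.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `"cort_states"` with `bin_labels` (one label
#'   per 1-s bin), `epochs` (data frame `state`, `start_s`, `end_s` with
#'   continuous boundaries) and `duration_s`.
#' @export
generate_state_sequence <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(substream_seed(cfg$seed, "state-sequence"))
  dur <- cfg$duration_s
  means <- cfg$state_mean_durations[.states2]
  a <- cfg$min_epoch_trunc_s

  # an infinite mean for one state means it never appears: the other
  # state occupies the whole recording
  one_state <- setdiff(.states2, .states2[is.infinite(means)])
  if (length(one_state) == 1) {
    epochs <- data.frame(state = one_state, start_s = 0, end_s = dur,
                         stringsAsFactors = FALSE)
    labels <- rep(one_state, floor(dur))
    return(structure(list(bin_labels = labels, epochs = epochs,
                          duration_s = dur), class = "cort_states"))
  }

  if (any(means <= a))
    stop("state mean durations must exceed the truncation point min_epoch_trunc_s")
  p_first <- means[["synchronized"]] / sum(means)
  first <- if (runif(1) < p_first) "synchronized" else "desynchronized"
  second <- setdiff(.states2, first)

  states <- character(0)
  durs <- numeric(0)
  total <- 0
  while (total < dur) {
    cur <- if (length(states) %% 2 == 0) first else second
    d <- a + rexp(1, 1 / (means[[cur]] - a))
    states <- c(states, cur)
    durs <- c(durs, d)
    total <- total + d
  }
  ends <- pmin(cumsum(durs), dur)
  starts <- c(0, head(ends, -1))
  epochs <- data.frame(state = states, start_s = starts, end_s = ends,
                       stringsAsFactors = FALSE)
  mids <- seq_len(floor(dur)) - 0.5
  labels <- states[findInterval(mids, starts)]

  st <- structure(list(bin_labels = labels, epochs = epochs,
                       duration_s = dur), class = "cort_states")
  if (!is.null(cfg$stim_times)) st <- apply_stimulation(st, cfg)
  st
}

# Stimulation paradigm: each stimulation is assumed delivered during the
# synchronized state and to evoke desynchronization.  Bin labels in the
# 2 s before onset are clamped synchronized; labels from onset to
# offset + stim_desync_s are clamped desynchronized.  Epochs are rebuilt
# from the modified labels.
apply_stimulation <- function(states, cfg) {
  lab <- states$bin_labels
  nb <- length(lab)
  for (t in cfg$stim_times) {
    pre <- seq.int(max(1, floor(t) - 1), max(1, floor(t)))
    post <- seq.int(floor(t) + 1,
                    min(nb, ceiling(t + cfg$stim_duration_s + cfg$stim_desync_s)))
    pre <- pre[pre >= 1 & pre <= nb]
    post <- post[post >= 1 & post <= nb]
    lab[pre] <- "synchronized"
    lab[post] <- "desynchronized"
  }
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  epochs <- data.frame(state = r$values,
                       start_s = c(0, head(ends, -1)),
                       end_s = ends, stringsAsFactors = FALSE)
  epochs$end_s[nrow(epochs)] <- states$duration_s
  states$bin_labels <- lab
  states$epochs <- epochs
  states
}

#' Generate up/down phase labels inside synchronized epochs
#'
#' Within every run of synchronized 1-s bins, alternating up and down
#' phases are drawn with exponential durations (configured means,
#' default 0.5 s each) and discretized at 10-ms bins.  Bins in
#' desynchronized periods are labeled `"na"`.  A `down` mean of 0 makes
#' the whole synchronized period one up phase (tonic firing).
#'
#' @param states A `cort_states` object.
#' @param cfg The [sim_config()] used to generate it.
#' @param bin_s Fine label resolution (s).
#' @return Character vector of `"up"`, `"down"`, `"na"` labels, one per
#'   fine bin, with attribute `bin_s`.
#' @export
generate_updown_phases <- function(states, cfg, bin_s = 0.01) {
  set.seed(substream_seed(cfg$seed, "updown-phases"))
  per_s <- round(1 / bin_s)
  nb <- length(states$bin_labels)
  n_fine <- nb * per_s
  lab <- rep("na", n_fine)
  mu <- cfg$updown_mean_durations
  r <- rle(states$bin_labels == "synchronized")
  ends <- cumsum(r$lengths)
  starts <- c(0, head(ends, -1))
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    i1 <- starts[i] * per_s + 1
    i2 <- ends[i] * per_s
    len <- r$lengths[i]
    if (mu[["down"]] == 0) {
      lab[i1:i2] <- "up"
      next
    }
    first_up <- runif(1) < mu[["up"]] / sum(mu)
    m1 <- if (first_up) mu[["up"]] else mu[["down"]]
    m2 <- if (first_up) mu[["down"]] else mu[["up"]]
    durs <- draw_alternating(len, m1, m2)
    phases <- rep(if (first_up) c("up", "down") else c("down", "up"),
                  length.out = length(durs))
    mids <- (seq_len(i2 - i1 + 1) - 0.5) * bin_s
    lab[i1:i2] <- phases[findInterval(mids, c(0, cumsum(durs)))]
  }
  attr(lab, "bin_s") <- bin_s
  lab
}

# Poisson spikes on a set of intervals at a constant rate.
sim_interval_poisson <- function(start, len, rate) {
  if (length(start) == 0 || rate <= 0) return(numeric(0))
  n <- rpois(length(start), len * rate)
  rep(start, n) + runif(sum(n)) * rep(len, n)
}

# Intervals (start, len) of fine bins with a given label.
label_intervals <- function(lab, value, bin_s) {
  r <- rle(lab == value)
  ends <- cumsum(r$lengths)
  starts <- c(0, head(ends, -1))
  keep <- r$values
  data.frame(start = starts[keep] * bin_s, len = r$lengths[keep] * bin_s)
}

#' Generate per-unit spike trains with ground truth
#'
#' Each unit fires as an inhomogeneous Poisson process: rate
#' `baseline / up_fraction` during up phases, 0 during down phases, and
#' `baseline * gain` during desynchronized periods, so that the
#' synchronized-state average rate equals the unit's baseline.  Each
#' spike independently initiates a doublet burst with probability
#' `burst_prob`, appending one extra spike at an exponential lag of mean
#' `burst_isi_ms`.  Extra spikes multiply all rates by
#' `(1 + burst_prob)`; ground-truth design rates record the totals.
#'
#' Per-unit baselines are drawn log-normally around the class mean
#' (arithmetic mean preserved) with spread `rate_spread_dex`, and
#' per-unit gains follow the class `gain_slope` in log-log coordinates.
#'
#' @param cfg A [sim_config()].
#' @param states A `cort_states` object.
#' @param updown Up/down labels from [generate_updown_phases()].
#' @return A list of class `"cort_units"` with `units` (per-unit table
#'   including ground-truth class, depth, rates and isolation distance)
#'   and `spikes` (data frame `unit_id`, `time_s`).
#' @export
generate_spike_trains <- function(cfg, states, updown) {
  bin_s <- attr(updown, "bin_s")
  set.seed(substream_seed(cfg$seed, "unit-params"))

  rows <- list()
  for (cl in names(cfg$class_params)) {
    p <- cfg$class_params[[cl]]
    n <- p$n_units
    if (n == 0) next
    s <- p$rate_spread_dex
    b <- p$baseline_rate_hz *
      10^rnorm(n, 0, s) / exp((s * log(10))^2 / 2)
    g <- p$desync_gain * 10^(p$gain_slope * (log10(b) - log10(p$baseline_rate_hz)))
    rows[[cl]] <- data.frame(
      class = cl,
      depth_um = runif(n, p$depth_range_um[1], p$depth_range_um[2]),
      baseline_hz = b,
      desync_gain = g,
      burst_prob = p$burst_prob,
      burst_isi_ms = p$burst_isi_ms,
      isolation_distance = runif(n, cfg$isolation_range[1], cfg$isolation_range[2]),
      stringsAsFactors = FALSE)
  }
  units <- do.call(rbind, rows)
  if (is.null(units))
    units <- data.frame(class = character(0), depth_um = numeric(0),
                        baseline_hz = numeric(0), desync_gain = numeric(0),
                        burst_prob = numeric(0), burst_isi_ms = numeric(0),
                        isolation_distance = numeric(0))
  rownames(units) <- NULL
  units$unit_id <- sprintf("u%03d", seq_len(nrow(units)))
  units <- units[, c("unit_id", setdiff(names(units), "unit_id"))]

  up_iv <- label_intervals(updown, "up", bin_s)
  sync_s <- sum(states$bin_labels == "synchronized")
  up_frac <- if (sync_s > 0) sum(up_iv$len) / sync_s else NA_real_
  de_r <- rle(states$bin_labels == "desynchronized")
  de_ends <- cumsum(de_r$lengths)
  de_iv <- data.frame(start = c(0, head(de_ends, -1))[de_r$values],
                      len = de_r$lengths[de_r$values])

  units$true_fr_s <- units$baseline_hz * (1 + units$burst_prob)
  units$true_fr_d <- units$baseline_hz * units$desync_gain * (1 + units$burst_prob)

  spk <- vector("list", nrow(units))
  for (i in seq_len(nrow(units))) {
    u <- units[i, ]
    set.seed(substream_seed(cfg$seed, paste0("spikes:", u$unit_id)))
    t_sync <- numeric(0)
    if (isTRUE(up_frac > 0)) {
      r_up <- u$baseline_hz / up_frac
      if (r_up * (1 + u$burst_prob) > 1000 / u$burst_isi_ms)
        warning(u$unit_id, ": up-phase rate ", round(r_up, 1),
                " Hz exceeds the burst-lag feasibility ceiling")
      t_sync <- sim_interval_poisson(up_iv$start, up_iv$len, r_up)
    }
    t_de <- sim_interval_poisson(de_iv$start, de_iv$len,
                                 u$baseline_hz * u$desync_gain)
    tt <- c(t_sync, t_de)
    if (u$burst_prob > 0 && length(tt) > 0) {
      sel <- runif(length(tt)) < u$burst_prob
      extras <- tt[sel] + rexp(sum(sel), 1000 / u$burst_isi_ms)
      tt <- c(tt, extras)
    }
    tt <- sort(tt[tt >= 0 & tt < states$duration_s])
    spk[[i]] <- if (length(tt)) data.frame(unit_id = u$unit_id, time_s = tt,
                                           stringsAsFactors = FALSE) else NULL
  }
  spikes <- do.call(rbind, spk)
  if (is.null(spikes)) spikes <- data.frame(unit_id = character(0), time_s = numeric(0))
  rownames(spikes) <- NULL

  structure(list(units = units, spikes = spikes, waveforms = NULL,
                 waveform_fs = cfg$waveform_fs,
                 channel_depths_um = channel_depths(cfg)),
            class = "cort_units")
}

#' Parametric biphasic spike waveform template
#'
#' A sum of three Gaussians — a negative trough flanked by two positive
#' bumps — solved in closed form so that the extracted features (trough
#' to peak time, half-amplitude width of the trough, asymmetry index of
#' the two baseline-to-peak amplitudes) equal the request.
#'
#' @param trough_to_peak_ms Time from trough to the following positive
#'   peak (ms).
#' @param half_width_ms Width of the trough at half its
#'   baseline-to-trough amplitude (ms).
#' @param asymmetry Target asymmetry index `(aR - aL)/(aR + aL)` in
#'   `(-1, 1]`.
#' @param fs Sampling rate (Hz).
#' @param half_window_ms Half-length of the waveform window (ms).
#' @return Numeric waveform with unit trough depth, attribute `fs`.
#' @export
waveform_template <- function(trough_to_peak_ms, half_width_ms, asymmetry,
                              fs = 20000, half_window_ms = 2) {
  ttp <- trough_to_peak_ms
  hw <- half_width_ms
  if (!is.finite(ttp) || ttp <= 0 || !is.finite(hw) || hw <= 0)
    stop("waveform features must be positive")
  if (asymmetry <= -1 || asymmetry > 1)
    stop("asymmetry must lie in (-1, 1]")
  if (ttp < 1.3 * hw)
    stop("unrealizable template: trough_to_peak_ms must be at least 1.3 x half_width_ms")
  sigma_p <- ttp / 5
  if (half_window_ms < ttp + 4 * sigma_p)
    stop("unrealizable template: window too short for requested trough-to-peak time")
  sigma_t <- hw / (2 * sqrt(2 * log(2)))
  aR <- 0.5
  aL <- aR * (1 - asymmetry) / (1 + asymmetry)
  t_ms <- seq(-half_window_ms, half_window_ms, by = 1000 / fs)
  w <- -exp(-t_ms^2 / (2 * sigma_t^2)) +
    aR * exp(-(t_ms - ttp)^2 / (2 * sigma_p^2)) +
    aL * exp(-(t_ms + ttp)^2 / (2 * sigma_p^2))
  attr(w, "fs") <- fs
  w
}

#' Generate per-unit, per-channel mean waveforms
#'
#' Each unit receives its class template (unit trough depth scaled to
#' `cfg$waveform_amp_uv`) on the channel nearest its depth, with
#' amplitude decaying over neighboring channels as a Gaussian in depth
#' distance (`cfg$waveform_decay_um`).  Independent Gaussian per-sample
#' noise of sd `waveform_noise_sd * waveform_amp_uv` is added on every
#' channel.
#'
#' @param cfg A [sim_config()].
#' @param units A `cort_units` object from [generate_spike_trains()].
#' @return The `cort_units` object with `waveforms` filled in (a named
#'   list of channels x samples matrices).
#' @export
generate_waveform_templates <- function(cfg, units) {
  set.seed(substream_seed(cfg$seed, "waveform-noise"))
  depths <- channel_depths(cfg)
  wf <- list()
  for (i in seq_len(nrow(units$units))) {
    u <- units$units[i, ]
    p <- cfg$class_params[[u$class]]$waveform
    tpl <- waveform_template(p$trough_to_peak_ms, p$half_width_ms, p$asymmetry,
                             fs = cfg$waveform_fs)
    scale <- cfg$waveform_amp_uv *
      exp(-(depths - u$depth_um)^2 / (2 * cfg$waveform_decay_um^2))
    m <- outer(scale, as.numeric(tpl))
    if (cfg$waveform_noise_sd > 0)
      m <- m + rnorm(length(m), 0, cfg$waveform_noise_sd * cfg$waveform_amp_uv)
    wf[[u$unit_id]] <- m
  }
  units$waveforms <- wf
  units
}

#' Generate the LFP matrix
#'
#' The LFP is broadband Gaussian noise (`noise_amp` microvolts sd) on
#' every channel, plus — during synchronized periods — a slow component
#' of amplitude `sync_osc_amp` sign-locked to the up/down labels
#' (negative during up phases, positive during down phases), whose
#' fundamental frequency is about `1 / (up mean + down mean)` Hz, and a
#' continuous within-phase oscillation at `sync_osc_freq_hz` (amplitude
#' `0.3 * sync_osc_amp`) standing in for the sustained low-frequency
#' activity of the synchronized state.  The 0-7 Hz band power is
#' therefore high in every synchronized bin — including bins spent
#' entirely inside one up or down phase — and low in desynchronized
#' bins.
#'
#' @param cfg A [sim_config()].
#' @param states A `cort_states` object.
#' @param updown Labels from [generate_updown_phases()].
#' @return A list of class `"cort_recording"`: `lfp` (frames x channels
#'   matrix, microvolts), `fs`, `channel_depths_um`, `stim_times`.
#' @export
generate_lfp <- function(cfg, states, updown) {
  set.seed(substream_seed(cfg$seed, "lfp-noise"))
  bin_s <- attr(updown, "bin_s")
  per <- round(cfg$lfp_fs * bin_s)
  if (abs(per - cfg$lfp_fs * bin_s) > 1e-9)
    stop("lfp_fs must be a multiple of the up/down label resolution")
  sign_f <- c(up = -1, down = 1, na = 0)[updown]
  slow <- rep(sign_f, each = per)
  n <- length(slow)
  amp <- cfg$lfp_params$sync_osc_amp
  f_osc <- cfg$lfp_params$sync_osc_freq_hz
  if (is.null(f_osc)) f_osc <- 3
  tt <- (seq_len(n) - 1) / cfg$lfp_fs
  in_sync <- rep(updown != "na", each = per)
  intra <- 0.3 * amp * sin(2 * pi * f_osc * tt) * in_sync
  lfp <- matrix(rnorm(n * cfg$n_channels, 0, cfg$lfp_params$noise_amp),
                n, cfg$n_channels)
  lfp <- lfp + amp * slow + intra
  structure(list(lfp = lfp, fs = cfg$lfp_fs,
                 channel_depths_um = channel_depths(cfg),
                 stim_times = cfg$stim_times),
            class = "cort_recording")
}

#' Simulate a complete recording in memory
#'
#' Runs every generator stage from one seed: state sequence, up/down
#' phases, spike trains, waveform templates and LFP.
#'
#' @param cfg A [sim_config()].
#' @param lfp Set `FALSE` to skip LFP synthesis (spike-only studies).
#' @param waveforms Set `FALSE` to skip waveform templates.
#' @return A list of class `"cort_sim"` with `config`, `states`,
#'   `updown`, `units` and (optionally) `recording`.
#' @export
simulate_recording <- function(cfg, lfp = TRUE, waveforms = TRUE) {
  states <- generate_state_sequence(cfg)
  updown <- generate_updown_phases(states, cfg)
  units <- generate_spike_trains(cfg, states, updown)
  if (waveforms) units <- generate_waveform_templates(cfg, units)
  rec <- if (lfp) generate_lfp(cfg, states, updown) else NULL
  structure(list(config = cfg, states = states, updown = updown,
                 units = units, recording = rec),
            class = "cort_sim")
}
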