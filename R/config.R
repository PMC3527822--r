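# Simulation configuration: the free parameters of the synthetic laminar
# recording generator.  The two condition presets encode the study
# conditions the pipeline is validated against: mean epoch durations of the
# two cortical states and class-wise baseline firing rates under urethane
# anesthesia and in unanesthetized head-fixed animals.

#' Per-class generator parameters
#'
#' Build the parameter block for one simulated cell class.
#'
#' @param n_units Number of units in the class.
#' @param baseline_rate_hz Class mean firing rate in the synchronized
#'   state (Hz).  Per-unit baselines are drawn log-normally around this
#'   value with the arithmetic mean preserved.
#' @param desync_gain Ratio of desynchronized to synchronized firing rate
#'   (`FR_d / FR_s`) at the class baseline rate.
#' @param burst_prob Probability that a spike initiates a doublet burst
#'   (one extra spike at a short lag).
#' @param burst_isi_ms Mean lag of the doublet's extra spike (ms); lags
#'   are exponential with this mean.
#' @param depth_range_um Two-element range of unit depths below the pia
#'   (micrometers).
#' @param waveform List with `trough_to_peak_ms`, `half_width_ms` and
#'   `asymmetry` defining the class mean spike waveform shape.
#' @param rate_spread_dex Log10 standard deviation of per-unit baseline
#'   rates around the class mean (0 = all units at the class rate).
#' @param gain_slope Dependence of a unit's log10 desynchronization gain
#'   on its log10 baseline rate, centered on the class baseline.  A
#'   positive slope makes high-rate units relatively enhanced during
#'   desynchronization.
#' @return A named list of class `"class_param"`.
#' @export
class_param <- function(n_units, baseline_rate_hz, desync_gain,
                        burst_prob = 0, burst_isi_ms = 5,
                        depth_range_um = c(0, 1600),
                        waveform = list(trough_to_peak_ms = 0.70,
                                        half_width_ms = 0.35,
                                        asymmetry = 0.10),
                        rate_spread_dex = 0, gain_slope = 0) {
  p <- list(n_units = as.integer(n_units),
            baseline_rate_hz = baseline_rate_hz,
            desync_gain = desync_gain,
            burst_prob = burst_prob,
            burst_isi_ms = burst_isi_ms,
            depth_range_um = depth_range_um,
            waveform = waveform,
            rate_spread_dex = rate_spread_dex,
            gain_slope = gain_slope)
  class(p) <- "class_param"
  p
}

#' Default class parameters for a recording condition
#'
#' Returns generator parameters for the four cell classes (superficial
#' and deep pyramidal cells, superficial and deep fast-spiking
#' interneurons).  Baseline rates are the condition-specific class means
#' (anesthetized: 0.9, 3.0, 5.8, 5.1 Hz; unanesthetized: 2.2, 4.5, 7.5,
#' 13.5 Hz for sPC, dPC, sFS, dFS).  Desynchronization gains encode the
#' qualitative laminar pattern the pipeline is designed to resolve:
#' superficial PCs and FS cells of both layers suppressed, deep PCs
#' heterogeneous with gain increasing with baseline rate.
#'
#' @param condition `"anesthetized"` or `"unanesthetized"`.
#' @return Named list of [class_param()] blocks (`sPC`, `dPC`, `sFS`,
#'   `dFS`).
#' @export
default_class_params <- function(condition = c("anesthetized", "unanesthetized")) {
  condition <- match.arg(condition)
  pc_wave <- list(trough_to_peak_ms = 0.70, half_width_ms = 0.35, asymmetry = 0.10)
  fs_wave <- list(trough_to_peak_ms = 0.35, half_width_ms = 0.20, asymmetry = 0.40)
  sup <- c(100, 500)
  deep <- c(800, 1100)
  if (condition == "anesthetized") {
    rates <- c(sPC = 0.9, dPC = 3.0, sFS = 5.8, dFS = 5.1)
    gains <- c(sPC = 0.45, dPC = 1.0, sFS = 0.50, dFS = 0.65)
  } else {
    rates <- c(sPC = 2.2, dPC = 4.5, sFS = 7.5, dFS = 13.5)
    gains <- c(sPC = 0.50, dPC = 0.90, sFS = 0.50, dFS = 0.60)
  }
  n <- c(sPC = 12L, dPC = 30L, sFS = 8L, dFS = 12L)
  spread <- c(sPC = 0.20, dPC = 0.30, sFS = 0.20, dFS = 0.20)
  slope <- c(sPC = 0, dPC = 0.7, sFS = 0, dFS = 0)
  out <- list()
  for (cl in .classes4) {
    out[[cl]] <- class_param(
      n_units = n[[cl]],
      baseline_rate_hz = rates[[cl]],
      desync_gain = gains[[cl]],
      depth_range_um = if (substr(cl, 1, 1) == "s") sup else deep,
      waveform = if (grepl("PC", cl)) pc_wave else fs_wave,
      rate_spread_dex = spread[[cl]],
      gain_slope = slope[[cl]])
  }
  out
}

#' Simulation configuration
#'
#' Assemble and validate the full parameter set of the synthetic laminar
#' recording generator.  Defaults follow the chosen `condition` preset:
#' state epoch duration means (anesthetized 167/165 s, unanesthetized
#' 197/423 s for synchronized/desynchronized), class baseline rates, and
#' the laminar gain pattern of [default_class_params()].
#'
#' Epoch durations are left-truncated exponential (no epoch shorter
#' than `min_epoch_trunc_s`), parameterized so the realized mean equals
#' the configured per-state mean.  A mean of `Inf` for one state
#' produces a single-state recording.
#'
#' @param duration_s Recording duration (s).
#' @param n_channels Number of probe channels.
#' @param channel_spacing_um Inter-channel spacing (micrometers); channel
#'   depths are `0, spacing, 2*spacing, ...` below the pia.
#' @param lfp_fs LFP sampling rate (Hz).
#' @param condition Preset, `"anesthetized"` or `"unanesthetized"`.
#' @param state_mean_durations Named numeric,
#'   `c(synchronized = , desynchronized = )` mean epoch durations (s);
#'   default per `condition`.
#' @param updown_mean_durations Named numeric, `c(up = , down = )` mean
#'   phase durations (s) inside synchronized epochs.  A `down` mean of 0
#'   makes synchronized firing tonic (homogeneous Poisson).
#' @param min_epoch_trunc_s Lower truncation of epoch durations (s).
#' @param class_params Named list of [class_param()] blocks; default per
#'   `condition`.
#' @param lfp_params List with `sync_osc_amp` and `noise_amp`
#'   (microvolts): amplitude of the slow oscillation that is sign-locked
#'   to up/down phases during synchronized epochs, and of the broadband
#'   noise present throughout; `sync_osc_freq_hz` sets the frequency of
#'   the continuous within-phase oscillation (0.3 x `sync_osc_amp`)
#'   present during synchronized periods.
#' @param waveform_fs Waveform sampling rate (Hz).
#' @param waveform_amp_uv Baseline-to-trough amplitude of the mean spike
#'   waveform on the soma channel (microvolts).
#' @param waveform_noise_sd Per-sample waveform noise, as a fraction of
#'   the soma trough amplitude.
#' @param waveform_decay_um Gaussian spatial decay constant of waveform
#'   amplitude across channels (micrometers).
#' @param isolation_range Range from which per-unit isolation distances
#'   are drawn uniformly.
#' @param stim_times Optional vector of stimulation onset times (s); each
#'   stimulation forces the desynchronized state for a few seconds after
#'   its offset (the evoked-desynchronization paradigm).
#' @param stim_duration_s Stimulation train duration (s).
#' @param stim_desync_s Duration of the forced desynchronized period
#'   after stimulation offset (s).
#' @param seed Master integer seed.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(duration_s = 1800,
                       n_channels = 16,
                       channel_spacing_um = 100,
                       lfp_fs = 1000,
                       condition = c("anesthetized", "unanesthetized"),
                       state_mean_durations = NULL,
                       updown_mean_durations = c(up = 0.5, down = 0.5),
                       min_epoch_trunc_s = 10,
                       class_params = NULL,
                       lfp_params = list(sync_osc_amp = 200, noise_amp = 20,
                                         sync_osc_freq_hz = 3),
                       waveform_fs = 20000,
                       waveform_amp_uv = 100,
                       waveform_noise_sd = 0.05,
                       waveform_decay_um = 50,
                       isolation_range = c(25, 55),
                       stim_times = NULL,
                       stim_duration_s = 1,
                       stim_desync_s = 4,
                       seed = 1) {
  condition <- match.arg(condition)
  if (is.null(state_mean_durations)) {
    state_mean_durations <- if (condition == "anesthetized") {
      c(synchronized = 167, desynchronized = 165)
    } else {
      c(synchronized = 197, desynchronized = 423)
    }
  }
  if (is.null(class_params)) class_params <- default_class_params(condition)
  cfg <- list(duration_s = duration_s,
              n_channels = as.integer(n_channels),
              channel_spacing_um = channel_spacing_um,
              lfp_fs = lfp_fs,
              condition = condition,
              state_mean_durations = state_mean_durations,
              updown_mean_durations = updown_mean_durations,
              min_epoch_trunc_s = min_epoch_trunc_s,
              class_params = class_params,
              lfp_params = lfp_params,
              waveform_fs = waveform_fs,
              waveform_amp_uv = waveform_amp_uv,
              waveform_noise_sd = waveform_noise_sd,
              waveform_decay_um = waveform_decay_um,
              isolation_range = isolation_range,
              stim_times = stim_times,
              stim_duration_s = stim_duration_s,
              stim_desync_s = stim_desync_s,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param cfg A `sim_config` object.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  err <- function(msg) stop("invalid config: ", msg, call. = FALSE)
  if (!is.finite(cfg$duration_s) || cfg$duration_s <= 0) err("duration_s must be > 0")
  if (cfg$n_channels < 1) err("n_channels must be >= 1")
  if (cfg$channel_spacing_um <= 0) err("channel_spacing_um must be > 0")
  if (cfg$lfp_fs <= 0) err("lfp_fs must be > 0")
  sm <- cfg$state_mean_durations
  if (!all(.states2 %in% names(sm))) err("state_mean_durations needs synchronized and desynchronized")
  if (any(sm <= 0, na.rm = TRUE)) err("state mean durations must be > 0")
  if (all(is.infinite(sm))) err("at most one state mean may be infinite")
  ud <- cfg$updown_mean_durations
  if (!all(c("up", "down") %in% names(ud))) err("updown_mean_durations needs up and down")
  if (ud[["up"]] <= 0) err("up phase mean must be > 0")
  if (ud[["down"]] < 0) err("down phase mean must be >= 0")
  if (cfg$min_epoch_trunc_s < 0) err("min_epoch_trunc_s must be >= 0")
  lp <- cfg$lfp_params
  if (lp$sync_osc_amp < 0 || lp$noise_amp < 0) err("LFP amplitudes must be >= 0")
  for (nm in names(cfg$class_params)) {
    p <- cfg$class_params[[nm]]
    if (p$n_units < 0) err(paste0(nm, ": n_units must be >= 0"))
    if (p$baseline_rate_hz <= 0) err(paste0(nm, ": baseline_rate_hz must be > 0"))
    if (p$desync_gain < 0) err(paste0(nm, ": desync_gain must be >= 0"))
    if (p$burst_prob < 0 || p$burst_prob > 1) err(paste0(nm, ": burst_prob must be in [0,1]"))
    if (p$burst_isi_ms <= 0) err(paste0(nm, ": burst_isi_ms must be > 0"))
    dr <- p$depth_range_um
    if (dr[1] < 0 || dr[2] > 1600 || dr[1] > dr[2])
      err(paste0(nm, ": depth_range_um must lie within [0, 1600]"))
  }
  invisible(cfg)
}

#' Serialize a simulation configuration to JSON
#'
#' Round-trip-safe JSON (de)serialization: named duration vectors are
#' written as objects so their names survive, and the result of
#' [read_sim_config()] is revalidated through [sim_config()].  Infinite
#' state means (single-state mode) are not representable in JSON and are
#' rejected.
#'
#' @param cfg A `sim_config`.
#' @param path JSON file path.
#' @return `path` (write) or the reconstructed `sim_config` (read).
#' @export
write_sim_config <- function(cfg, path) {
  validate_sim_config(cfg)
  if (any(is.infinite(cfg$state_mean_durations)))
    stop("infinite state means cannot be serialized")
  l <- unclass(cfg)
  l$state_mean_durations <- as.list(l$state_mean_durations)
  l$updown_mean_durations <- as.list(l$updown_mean_durations)
  l$class_params <- lapply(l$class_params, unclass)
  jsonlite::write_json(l, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  cp <- lapply(l$class_params, function(p) do.call(class_param, p))
  sim_config(duration_s = l$duration_s,
             n_channels = l$n_channels,
             channel_spacing_um = l$channel_spacing_um,
             lfp_fs = l$lfp_fs,
             condition = l$condition,
             state_mean_durations = unlist(l$state_mean_durations),
             updown_mean_durations = unlist(l$updown_mean_durations),
             min_epoch_trunc_s = l$min_epoch_trunc_s,
             class_params = cp,
             lfp_params = l$lfp_params,
             waveform_fs = l$waveform_fs,
             waveform_amp_uv = l$waveform_amp_uv,
             waveform_noise_sd = l$waveform_noise_sd,
             waveform_decay_um = l$waveform_decay_um,
             isolation_range = l$isolation_range,
             stim_times = l$stim_times,
             stim_duration_s = l$stim_duration_s,
             stim_desync_s = l$stim_desync_s,
             seed = l$seed)
}

#' Channel depths implied by a configuration
#' @param cfg A `sim_config`.
#' @return Numeric vector of channel depths (micrometers, ascending).
#' @export
channel_depths <- function(cfg) {
  (seq_len(cfg$n_channels) - 1) * cfg$channel_spacing_um
}
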