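# Small configurations and truth-level helpers shared across tests.

# One-class configuration with everything not under study switched off.
one_class_cfg <- function(n_units = 1, rate = 3, gain = 1, burst_prob = 0,
                          duration_s = 600, seed = 1, condition = "anesthetized",
                          state_means = NULL, updown = c(up = 0.5, down = 0.5),
                          depth_range = c(800, 1100), class = "dPC", ...) {
  cp <- list(class_param(n_units, rate, gain, burst_prob = burst_prob,
                         depth_range_um = depth_range))
  names(cp) <- class
  sim_config(duration_s = duration_s, n_channels = 1, condition = condition,
             state_mean_durations = state_means,
             updown_mean_durations = updown,
             class_params = cp, seed = seed, ...)
}

# Segmentation object built from ground-truth state labels, for tests that
# calibrate the statistics independently of LFP-based detection.
truth_segmentation <- function(states) {
  r <- rle(states$bin_labels)
  ends <- cumsum(r$lengths)
  structure(list(bin_labels = states$bin_labels,
                 epochs = data.frame(state = r$values,
                                     start_s = c(0, utils::head(ends, -1)),
                                     end_s = ends, stringsAsFactors = FALSE),
                 bin_s = 1, n_bins = length(states$bin_labels),
                 status = "truth", updown = NULL),
            class = "cort_segmentation")
}

# A segmentation with a single synchronized epoch covering n_bins seconds.
all_sync_segmentation <- function(n_bins) {
  structure(list(bin_labels = rep("synchronized", n_bins),
                 epochs = data.frame(state = "synchronized", start_s = 0,
                                     end_s = n_bins, stringsAsFactors = FALSE),
                 bin_s = 1, n_bins = n_bins, status = "truth", updown = NULL),
            class = "cort_segmentation")
}

spikes_of <- function(sim, unit_id) {
  sim$units$spikes$time_s[sim$units$spikes$unit_id == unit_id]
}

true_class2 <- function(sim) {
  ifelse(grepl("PC", sim$units$units$class), "PC", "FS")
}
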