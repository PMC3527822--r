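# State segmentation: per-1-s-bin 0-7 Hz LFP power, two-state
# classification of its logarithm, up/down phase detection from pooled
# multiunit activity, and pre/post windows around stimulation events.

hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))

#' Low-frequency LFP band power per 1-s bin
#'
#' For every non-overlapping bin, the signal is demeaned, Hann-tapered
#' and Fourier-transformed; power is summed over frequencies inside the
#' band (DC excluded), normalized so that the total over all frequencies
#' equals the taper-weighted signal variance (Parseval).
#'
#' @param rec A `cort_recording`, or a numeric vector (then `fs` is
#'   required).
#' @param channel Channel index; default is the first channel of the
#'   deepest third of the probe (infragranular bias).  Use
#'   `channel = "mean"` to average band power over all channels.
#' @param fs Sampling rate (Hz), when `rec` is a bare vector.
#' @param band_hz Frequency band, default `c(0, 7)`; power is taken over
#'   `(band[1], band[2]]`.
#' @param bin_s Bin length (s).
#' @return Data frame of class `"cort_power"` with `bin_start_s`,
#'   `power` (signal units squared) and `log_power` (log10; `NA` where
#'   power is 0, flagged via the `"zero_power_bins"` attribute).
#' @export
compute_low_freq_power <- function(rec, channel = NULL, fs = NULL,
                                   band_hz = c(0, 7), bin_s = 1) {
  if (inherits(rec, "cort_recording")) {
    fs <- rec$fs
    nch <- ncol(rec$lfp)
    if (identical(channel, "mean")) {
      out <- NULL
      for (ch in seq_len(nch)) {
        p <- compute_low_freq_power(rec$lfp[, ch], fs = fs,
                                    band_hz = band_hz, bin_s = bin_s)
        out <- if (is.null(out)) p else {out$power <- out$power + p$power; out}
      }
      out$power <- out$power / nch
      out$log_power <- ifelse(out$power > 0, log10(out$power), NA_real_)
      attr(out, "zero_power_bins") <- which(out$power == 0)
      return(out)
    }
    if (is.null(channel)) channel <- floor(2 * nch / 3) + 1
    x <- rec$lfp[, channel]
  } else {
    x <- as.numeric(rec)
    if (is.null(fs)) stop("fs is required when rec is a numeric vector")
  }
  if (fs <= 2 * band_hz[2]) stop("sampling rate must exceed twice the band upper edge")
  n <- round(fs * bin_s)
  nb <- floor(length(x) / n)
  if (nb < 2) stop("recording must span at least 2 bins")
  m <- matrix(x[seq_len(nb * n)], n, nb)
  m <- sweep(m, 2, colMeans(m))
  w <- hann(n)
  sp <- Mod(mvfft(m * w))^2
  f <- (seq_len(n) - 1) * fs / n
  idx <- which(f > band_hz[1] & f <= band_hz[2])
  power <- 2 * colSums(sp[idx, , drop = FALSE]) / (n * sum(w^2))
  out <- data.frame(bin_start_s = (seq_len(nb) - 1) * bin_s,
                    power = power,
                    log_power = ifelse(power > 0, log10(power), NA_real_))
  class(out) <- c("cort_power", "data.frame")
  attr(out, "bin_s") <- bin_s
  attr(out, "zero_power_bins") <- which(power == 0)
  out
}

merge_short_runs <- function(y, min_len) {
  repeat {
    r <- rle(y)
    if (length(r$lengths) <= 1) break
    i <- which.min(r$lengths)
    if (r$lengths[i] >= min_len) break
    r$values[i] <- if (i > 1) r$values[i - 1] else r$values[i + 1]
    y <- inverse.rle(r)
  }
  y
}

#' Classify 1-s bins into synchronized and desynchronized states
#'
#' Splits the per-bin log band power into two classes with 1-D k-means
#' (k = 2, centers initialized at the data minimum and maximum, so the
#' result is deterministic); the lower-power cluster is labeled
#' desynchronized.  Labels are median-smoothed over `smooth_bins` bins
#' and runs shorter than `min_epoch_s` are merged into their neighbors.
#' If the two cluster centers are separated by less than 1% of the
#' log-power range, no state alternation is detectable: all bins are
#' labeled by comparison with the global median, with a warning, and
#' `status` is `"degenerate"`.
#'
#' @param ps A `cort_power` series from [compute_low_freq_power()].
#' @param min_epoch_s Minimum epoch duration retained (s).
#' @param smooth_bins Median smoothing window (odd number of bins).
#' @return A list of class `"cort_segmentation"`: `bin_labels`,
#'   `epochs` (data frame `state`, `start_s`, `end_s`), `bin_s`,
#'   `status` (`"ok"` or `"degenerate"`), `updown` (`NULL` until
#'   [detect_updown()] is run).
#' @export
classify_states <- function(ps, min_epoch_s = 10, smooth_bins = 5) {
  x <- ps$log_power
  bin_s <- attr(ps, "bin_s")
  if (is.null(bin_s)) bin_s <- 1
  ok <- is.finite(x)
  status <- "ok"
  nb <- length(x)
  sync <- logical(nb)
  rng <- if (any(ok)) diff(range(x[ok])) else 0
  degenerate <- sum(ok) < 2 || rng == 0
  if (!degenerate) {
    km <- kmeans(x[ok], centers = matrix(c(min(x[ok]), max(x[ok])), 2, 1))
    if (abs(diff(km$centers)) < 0.01 * rng) degenerate <- TRUE
    else sync[ok] <- km$cluster == which.max(km$centers)
  }
  if (degenerate) {
    status <- "degenerate"
    warning("no state alternation detected; labeling by global median power")
    sync <- ps$power > median(ps$power)
  }
  y <- as.integer(sync)
  if (!degenerate && nb >= smooth_bins) y <- as.integer(runmed(y, smooth_bins))
  if (!degenerate) y <- merge_short_runs(y, ceiling(min_epoch_s / bin_s))
  labels <- ifelse(y == 1, "synchronized", "desynchronized")
  r <- rle(labels)
  ends <- cumsum(r$lengths) * bin_s
  epochs <- data.frame(state = r$values, start_s = c(0, head(ends, -1)),
                       end_s = ends, stringsAsFactors = FALSE)
  structure(list(bin_labels = labels, epochs = epochs, bin_s = bin_s,
                 n_bins = nb, status = status, updown = NULL),
            class = "cort_segmentation")
}

#' Detect up and down phases from multiunit activity
#'
#' Pools all spikes, counts them in `bin_ms` bins, smooths the counts
#' with a Gaussian kernel (`smooth_sigma_ms`), and thresholds within
#' each synchronized epoch at `threshold_frac` of the mean up-phase
#' rate.  The threshold is iterated twice: first against the epoch mean
#' rate, then against the mean rate of the provisional up bins.  Fine
#' bins in desynchronized periods are labeled `"na"`.  If the pooled
#' synchronized-state rate is below `min_rate_hz`, all synchronized bins
#' are labeled `"down"` and the result is flagged `low_rate`.
#'
#' @param spikes Numeric vector of pooled spike times (s), or a
#'   `cort_units` object (all units pooled).
#' @param seg A `cort_segmentation`.
#' @param bin_ms Fine bin width (ms).
#' @param smooth_sigma_ms Gaussian smoothing sd (ms).
#' @param threshold_frac Threshold as a fraction of the mean up rate.
#' @param min_rate_hz Minimum pooled rate for detection (Hz).
#' @return A list of class `"cort_updown"`: `labels` (per fine bin),
#'   `bin_s`, `flags`.
#' @export
detect_updown <- function(spikes, seg, bin_ms = 10, smooth_sigma_ms = 30,
                          threshold_frac = 0.2, min_rate_hz = 0.5) {
  if (inherits(spikes, "cort_units")) spikes <- spikes$spikes$time_s
  bin_s <- bin_ms / 1000
  per <- round(seg$bin_s / bin_s)
  nf <- seg$n_bins * per
  flags <- character(0)
  lab <- rep("na", nf)
  counts <- tabulate(findInterval(spikes, (seq_len(nf) - 1) * bin_s), nf)
  sig_bins <- smooth_sigma_ms / bin_ms
  half <- ceiling(4 * sig_bins)
  kern <- dnorm(-half:half, 0, sig_bins)
  kern <- kern / sum(kern)
  sm <- as.numeric(stats::filter(counts, kern, sides = 2))
  sm[is.na(sm)] <- counts[is.na(sm)]
  rate <- sm / bin_s

  r <- rle(seg$bin_labels == "synchronized")
  ends <- cumsum(r$lengths)
  starts <- c(0, head(ends, -1))
  sync_idx <- which(r$values)
  if (length(sync_idx) == 0) {
    return(structure(list(labels = lab, bin_s = bin_s, flags = flags),
                     class = "cort_updown"))
  }
  sync_time <- sum(r$lengths[sync_idx]) * seg$bin_s
  sync_fine <- unlist(lapply(sync_idx, function(i)
    seq.int(starts[i] * per + 1, ends[i] * per)))
  pooled_rate <- sum(counts[sync_fine]) / sync_time
  if (pooled_rate < min_rate_hz) {
    lab[sync_fine] <- "down"
    flags <- c(flags, "low_rate")
    return(structure(list(labels = lab, bin_s = bin_s, flags = flags),
                     class = "cort_updown"))
  }
  for (i in sync_idx) {
    idx <- seq.int(starts[i] * per + 1, ends[i] * per)
    rr <- rate[idx]
    th <- threshold_frac * mean(rr)
    up <- rr > th
    if (any(up)) {
      th <- threshold_frac * mean(rr[up])
      up <- rr > th
    }
    lab[idx] <- ifelse(up, "up", "down")
  }
  structure(list(labels = lab, bin_s = bin_s, flags = flags),
            class = "cort_updown")
}

#' Pre/post windows around stimulation events
#'
#' For each stimulation onset `t`, builds the 2-s windows immediately
#' before onset (`[t - 2, t)`) and immediately after offset
#' (`[t + stim_duration_s, t + stim_duration_s + 2)`).  A stimulation is
#' `effective` when the mean 0-7 Hz power of bins inside the post window
#' is below `drop_factor` times the pre-window mean (i.e. low-frequency
#' power collapsed).  Events whose windows fall outside the recording
#' are dropped; the count is stored in the `"n_dropped"` attribute.
#'
#' @param stim_times Stimulation onset times (s).
#' @param stim_duration_s Stimulation train duration (s).
#' @param ps A `cort_power` series.
#' @param window_s Window length (s).
#' @param drop_factor Required post/pre power ratio for effectiveness.
#' @return Data frame of class `"cort_stim_windows"` with columns
#'   `stim_time`, `pre_start`, `pre_end`, `post_start`, `post_end`,
#'   `effective`.
#' @export
build_stim_windows <- function(stim_times, stim_duration_s = 1, ps = NULL,
                               window_s = 2, drop_factor = 0.5) {
  if (length(stim_times) == 0) {
    out <- data.frame(stim_time = numeric(0), pre_start = numeric(0),
                      pre_end = numeric(0), post_start = numeric(0),
                      post_end = numeric(0), effective = logical(0))
    class(out) <- c("cort_stim_windows", "data.frame")
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  stim_times <- sort(stim_times)
  if (any(diff(stim_times) <= 2 * window_s + stim_duration_s))
    warning("stimulation events closer than ", 2 * window_s + stim_duration_s,
            " s; windows may overlap")
  out <- data.frame(stim_time = stim_times,
                    pre_start = stim_times - window_s,
                    pre_end = stim_times,
                    post_start = stim_times + stim_duration_s,
                    post_end = stim_times + stim_duration_s + window_s)
  dur <- if (!is.null(ps)) nrow(ps) * attr(ps, "bin_s") else Inf
  keep <- out$pre_start >= 0 & out$post_end <= dur
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " stimulation event(s) dropped near recording edges")
  out <- out[keep, , drop = FALSE]
  if (!is.null(ps) && nrow(out) > 0) {
    win_power <- function(a, b) {
      idx <- ps$bin_start_s >= a & (ps$bin_start_s + attr(ps, "bin_s")) <= b
      if (!any(idx)) NA_real_ else mean(ps$power[idx])
    }
    pre_p <- mapply(win_power, out$pre_start, out$pre_end)
    post_p <- mapply(win_power, out$post_start, out$post_end)
    out$effective <- post_p < drop_factor * pre_p
  } else {
    out$effective <- NA
  }
  rownames(out) <- NULL
  class(out) <- c("cort_stim_windows", "data.frame")
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Mean detected epoch duration per state
#'
#' Recovers the mean epoch duration of each state from one or more
#' segmentations.  The last epoch of a recording is right-censored by
#' the observation window; simply averaging the epochs that fit inside
#' the window under-represents long epochs and biases the mean
#' downward.  The default estimator is therefore the renewal-process
#' maximum-likelihood form: total time spent in the state (including
#' the censored tail) divided by the number of completed epochs of that
#' state.  Epochs beginning at time 0 are counted as complete, exact
#' for the simulator (whose recordings begin at an epoch onset) and a
#' mild approximation for recordings cut mid-epoch.
#'
#' @param seg A `cort_segmentation` (or a list of them, pooled).
#' @param method `"censoring"` (default, as above) or `"naive"` (mean
#'   of epochs not touching either recording edge).
#' @return Named numeric vector of mean durations (s) for the two
#'   states.
#' @export
epoch_duration_means <- function(seg, method = c("censoring", "naive")) {
  method <- match.arg(method)
  segs <- if (inherits(seg, "cort_segmentation")) list(seg) else seg
  total <- c(synchronized = 0, desynchronized = 0)
  n_complete <- c(synchronized = 0, desynchronized = 0)
  durs <- list(synchronized = numeric(0), desynchronized = numeric(0))
  for (s in segs) {
    e <- s$epochs
    dur_rec <- s$n_bins * s$bin_s
    for (st in .states2) {
      es <- e[e$state == st, , drop = FALSE]
      total[st] <- total[st] + sum(es$end_s - es$start_s)
      n_complete[st] <- n_complete[st] + sum(es$end_s < dur_rec)
      interior <- es$start_s > 0 & es$end_s < dur_rec
      durs[[st]] <- c(durs[[st]], es$end_s[interior] - es$start_s[interior])
    }
  }
  if (method == "naive")
    return(vapply(durs, function(d) if (length(d)) mean(d) else NA_real_,
                  numeric(1)))
  out <- ifelse(n_complete > 0, total / n_complete, NA_real_)
  names(out) <- .states2
  out
}
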