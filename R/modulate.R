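# State-dependent firing statistics: per-state firing rates (spontaneous
# 1-s-bin and evoked pre/post-window modes), the modulation index
# (FR_d - FR_s)/(FR_d + FR_s), per-cell significance tests, population
# signed-rank tests, burst-fraction analysis with its closed-form
# calibration, the baseline-rate-versus-modulation semi-log regression,
# layer-resolved multiunit modulation, and the population summary table.

#' Per-state firing rates from spontaneous state alternation
#'
#' Counts spikes in the 1-s bins of a segmentation; `FR_s` and `FR_d`
#' are the mean counts over synchronized and desynchronized bins.
#'
#' @param spikes Numeric spike times (s) of one unit.
#' @param seg A `cort_segmentation`.
#' @param min_bins Recommended minimum bins per state; fewer raises a
#'   `low_bins` flag.
#' @return A list of class `"cort_rates"`: `mode = "spontaneous"`,
#'   `fr_s`, `fr_d`, `counts_s`, `counts_d`, `available`, `flags`.
#' @export
rate_by_state_spontaneous <- function(spikes, seg, min_bins = 30) {
  nb <- seg$n_bins
  counts <- tabulate(findInterval(spikes, (seq_len(nb) - 1) * seg$bin_s), nb)
  sync <- seg$bin_labels == "synchronized"
  flags <- character(0)
  available <- any(sync) && any(!sync)
  if (!available) flags <- c(flags, "one_state_absent")
  if (sum(sync) < min_bins || sum(!sync) < min_bins)
    flags <- c(flags, "low_bins")
  fr_s <- if (any(sync)) mean(counts[sync]) / seg$bin_s else NA_real_
  fr_d <- if (any(!sync)) mean(counts[!sync]) / seg$bin_s else NA_real_
  structure(list(mode = "spontaneous", fr_s = fr_s, fr_d = fr_d,
                 counts_s = counts[sync], counts_d = counts[!sync],
                 available = available, flags = flags),
            class = "cort_rates")
}

#' Per-state firing rates from stimulation windows
#'
#' For each effective stimulation event, counts spikes in the 2-s pre
#' window (synchronized state) and post window (desynchronized state);
#' rates are counts divided by the window length, and `FR_s`/`FR_d` are
#' across-event means.
#'
#' @param spikes Numeric spike times (s) of one unit.
#' @param windows A `cort_stim_windows` data frame.
#' @param effective_only Use only events judged effective.
#' @param min_events Minimum number of usable events.
#' @return A list of class `"cort_rates"`: `mode = "evoked"`, `fr_s`,
#'   `fr_d`, per-event `counts_s` / `counts_d`, `available`, `flags`.
#' @export
rate_by_state_evoked <- function(spikes, windows, effective_only = TRUE,
                                 min_events = 5) {
  w <- windows
  if (effective_only) w <- w[!is.na(w$effective) & w$effective, , drop = FALSE]
  flags <- character(0)
  if (nrow(w) == 0) {
    return(structure(list(mode = "evoked", fr_s = NA_real_, fr_d = NA_real_,
                          counts_s = numeric(0), counts_d = numeric(0),
                          available = FALSE, flags = "no_effective_events"),
                     class = "cort_rates"))
  }
  if (nrow(w) < min_events) flags <- c(flags, "few_events")
  cnt <- function(a, b) vapply(seq_len(nrow(w)), function(i)
    sum(spikes >= a[i] & spikes < b[i]), numeric(1))
  pre <- cnt(w$pre_start, w$pre_end)
  post <- cnt(w$post_start, w$post_end)
  len <- w$pre_end - w$pre_start
  structure(list(mode = "evoked",
                 fr_s = mean(pre / len), fr_d = mean(post / len),
                 counts_s = pre, counts_d = post,
                 available = TRUE, flags = flags),
            class = "cort_rates")
}

#' State modulation index
#'
#' `MI = (FR_d - FR_s) / (FR_d + FR_s)`, bounded in `[-1, 1]`; positive
#' values mean firing enhanced by desynchronization.  Undefined (`NA`)
#' when both rates are 0 (such units are excluded from population
#' statistics).
#'
#' @param fr_d,fr_s Firing rates (Hz) in the desynchronized and
#'   synchronized states; vectorized.
#' @return Numeric modulation index.
#' @export
modulation_index <- function(fr_d, fr_s) {
  if (any(fr_d < 0, na.rm = TRUE) || any(fr_s < 0, na.rm = TRUE))
    stop("firing rates must be non-negative")
  ifelse(fr_d + fr_s > 0, (fr_d - fr_s) / (fr_d + fr_s), NA_real_)
}

#' Per-cell significance of the state-dependent rate change
#'
#' Spontaneous mode: Welch unpaired t-test between the per-1-s-bin spike
#' counts of the two states.  Evoked mode: paired t-test across
#' stimulation events on (post, pre) counts.  The significance class is
#' `enhanced` / `suppressed` by the sign of `FR_d - FR_s` when
#' `p < alpha`, else `ns`.  Zero variance in both samples leaves p
#' undefined and the unit `ns` with a flag.
#'
#' @param rates A `cort_rates` object.
#' @param alpha Significance level.
#' @return A list: `p_value`, `sig_class`, `mi`, `fr_s`, `fr_d`,
#'   `flags`.
#' @export
per_cell_significance <- function(rates, alpha = 0.05) {
  stopifnot(inherits(rates, "cort_rates"))
  flags <- rates$flags
  mi <- modulation_index(rates$fr_d, rates$fr_s)
  if (!rates$available) {
    return(list(p_value = NA_real_, sig_class = "ns", mi = mi,
                fr_s = rates$fr_s, fr_d = rates$fr_d,
                flags = c(flags, "mode_unavailable")))
  }
  p <- tryCatch({
    if (rates$mode == "evoked") {
      t.test(rates$counts_d, rates$counts_s, paired = TRUE)$p.value
    } else {
      t.test(rates$counts_d, rates$counts_s)$p.value
    }
  }, error = function(e) NA_real_)
  if (is.na(p)) flags <- c(flags, "zero_variance")
  sig <- "ns"
  if (!is.na(p) && p < alpha)
    sig <- if (rates$fr_d > rates$fr_s) "enhanced" else "suppressed"
  list(p_value = p, sig_class = sig, mi = mi,
       fr_s = rates$fr_s, fr_d = rates$fr_d, flags = flags)
}

#' Wilcoxon signed-rank test of modulation indices against zero
#'
#' Two-sided test of the median MI against 0: exact distribution for 25
#' or fewer non-zero values without ties, normal approximation with
#' continuity correction otherwise.  Zeros are dropped (Wilcoxon
#' convention); if nothing remains, p = 1.
#'
#' @param mi Numeric modulation indices (`NA` values dropped).
#' @param min_n Recommended minimum number of defined MIs.
#' @return A list: `median_mi`, `p_value`, `n`.
#' @export
population_signed_rank <- function(mi, min_n = 5) {
  mi <- mi[is.finite(mi)]
  med <- if (length(mi)) median(mi) else NA_real_
  x <- mi[mi != 0]
  if (length(x) == 0)
    return(list(median_mi = med, p_value = 1, n = length(mi)))
  if (length(mi) < min_n) warning("fewer than ", min_n, " defined MIs")
  exact <- length(x) <= 25 && !any(duplicated(abs(x)))
  p <- suppressWarnings(
    wilcox.test(x, mu = 0, exact = exact, correct = TRUE)$p.value)
  list(median_mi = med, p_value = p, n = length(mi))
}

#' Fraction of burst-like inter-spike intervals per state
#'
#' ISIs are formed within each state's epochs only (intervals spanning
#' an epoch boundary are discarded); the burst fraction is the share of
#' ISIs at or below the window.  Undefined for a state with fewer than
#' 2 spikes in some epoch-wise sense (no ISIs).
#'
#' @param spikes Numeric spike times (s) of one unit.
#' @param seg A `cort_segmentation`.
#' @param window_ms Burst window(s) in ms (any of 10, 15, 20, 25, ...).
#' @return Data frame with one row per window: `window_ms`,
#'   `frac_sync`, `frac_desync`, `n_isi_sync`, `n_isi_desync`.
#' @export
burst_fraction <- function(spikes, seg, window_ms = 20) {
  spikes <- sort(spikes)
  isis <- list(synchronized = numeric(0), desynchronized = numeric(0))
  for (i in seq_len(nrow(seg$epochs))) {
    e <- seg$epochs[i, ]
    s <- spikes[spikes >= e$start_s & spikes < e$end_s]
    if (length(s) >= 2) isis[[e$state]] <- c(isis[[e$state]], diff(s))
  }
  frac <- function(isi, w) if (length(isi)) mean(isi <= w / 1000) else NA_real_
  data.frame(window_ms = window_ms,
             frac_sync = vapply(window_ms, function(w) frac(isis$synchronized, w), numeric(1)),
             frac_desync = vapply(window_ms, function(w) frac(isis$desynchronized, w), numeric(1)),
             n_isi_sync = length(isis$synchronized),
             n_isi_desync = length(isis$desynchronized))
}

#' Closed-form burst fraction of the doublet generator
#'
#' Expected fraction of ISIs at or below a window for a simulated unit:
#' seed spikes are Poisson (rate `baseline / up_fraction` inside up
#' phases for the synchronized state, `baseline * desync_gain` for the
#' desynchronized state), and each seed spike adds a doublet spike with
#' probability `burst_prob` at an exponential lag of mean
#' `burst_isi_ms`.  Doublet ISIs fall inside the window with probability
#' `1 - exp(-w / lag)`, and seed-to-next-spike ISIs with probability
#' `lambda/(lambda + eta) * (1 - exp(-(lambda + eta) w))`, where `eta`
#' is the hazard of the up phase ending (competing risk of entering a
#' silent down phase); transitions that re-enter an up phase within the
#' window are neglected.
#'
#' @param baseline_rate_hz Unit baseline (synchronized-average) rate.
#' @param burst_prob Doublet probability.
#' @param burst_isi_ms Mean doublet lag (ms).
#' @param window_ms Burst window (ms).
#' @param state Which state's fraction to compute.
#' @param up_mean_s,down_mean_s Up/down phase duration means (s).
#' @param desync_gain Gain for the desynchronized state.
#' @return Expected burst fraction.
#' @export
analytic_burst_fraction <- function(baseline_rate_hz, burst_prob,
                                    burst_isi_ms = 5, window_ms = 20,
                                    state = c("synchronized", "desynchronized"),
                                    up_mean_s = 0.5, down_mean_s = 0.5,
                                    desync_gain = 1) {
  state <- match.arg(state)
  w <- window_ms / 1000
  p_lag <- 1 - exp(-window_ms / burst_isi_ms)
  if (state == "synchronized") {
    up_frac <- if (down_mean_s > 0) up_mean_s / (up_mean_s + down_mean_s) else 1
    lam <- baseline_rate_hz / up_frac
    eta <- if (down_mean_s > 0) 1 / up_mean_s else 0
  } else {
    lam <- baseline_rate_hz * desync_gain
    eta <- 0
  }
  s <- if (eta > 0) lam / (lam + eta) * (1 - exp(-(lam + eta) * w))
       else 1 - exp(-lam * w)
  (burst_prob * p_lag + s) / (1 + burst_prob)
}

#' Solve the doublet probability for a target burst fraction
#'
#' Inverts [analytic_burst_fraction()] for `burst_prob` in `[0, 1]`.
#' When the target lies below the Poisson floor (the fraction at
#' `burst_prob = 0`), the floor is the closest attainable value and 0
#' is returned with a warning; similarly 1 for targets above the
#' ceiling.
#'
#' @param target_frac Target burst fraction.
#' @param ... Passed to [analytic_burst_fraction()].
#' @return The doublet probability.
#' @export
solve_burst_prob <- function(target_frac, ...) {
  f <- function(p) analytic_burst_fraction(burst_prob = p, ...) - target_frac
  if (f(0) >= 0) {
    if (f(0) > 0)
      warning("target below the Poisson floor ",
              signif(f(0) + target_frac, 4), "; returning burst_prob = 0")
    return(0)
  }
  if (f(1) <= 0) {
    warning("target above the attainable ceiling; returning burst_prob = 1")
    return(1)
  }
  stats::uniroot(f, c(0, 1), tol = 1e-9)$root
}

#' Kruskal-Wallis and post-hoc rank-sum tests on burst fractions
#'
#' Kruskal-Wallis across all class-by-state groups, then for each class
#' a two-sided Wilcoxon rank-sum test between the synchronized and
#' desynchronized fractions.  No multiplicity correction is applied by
#' default, matching the per-class reporting style; set `p_adjust` to a
#' [stats::p.adjust()] method to correct the post-hoc p-values.
#'
#' @param bursts Data frame with one row per unit: `class`,
#'   `frac_sync`, `frac_desync`.
#' @param min_units Minimum units per class for the post-hoc test.
#' @param p_adjust `"none"` or a [stats::p.adjust()] method.
#' @return A list: `kruskal_p` and `class_tests` (data frame `class`,
#'   `n`, `p_value`).
#' @export
burst_state_comparison <- function(bursts, min_units = 5, p_adjust = "none") {
  keep <- is.finite(bursts$frac_sync) & is.finite(bursts$frac_desync)
  if (any(!keep)) warning(sum(!keep), " unit(s) without defined fractions dropped")
  bursts <- bursts[keep, , drop = FALSE]
  long <- data.frame(
    frac = c(bursts$frac_sync, bursts$frac_desync),
    group = factor(c(paste0(bursts$class, ".sync"), paste0(bursts$class, ".desync"))))
  kw_p <- if (nlevels(droplevels(long$group)) >= 2)
    kruskal.test(frac ~ group, data = long)$p.value else NA_real_
  classes <- unique(bursts$class)
  res <- lapply(classes, function(cl) {
    b <- bursts[bursts$class == cl, ]
    if (nrow(b) < min_units)
      return(data.frame(class = cl, n = nrow(b), p_value = NA_real_))
    p <- suppressWarnings(wilcox.test(b$frac_sync, b$frac_desync)$p.value)
    if (is.nan(p)) p <- 1                 # fully tied groups
    data.frame(class = cl, n = nrow(b), p_value = p)
  })
  res <- do.call(rbind, res)
  res$p_value <- stats::p.adjust(res$p_value, method = p_adjust)
  list(kruskal_p = kw_p, class_tests = res)
}

#' Baseline-rate versus modulation-index regression (semi-log)
#'
#' Pearson correlation and least-squares line between `log10(FR_s)` and
#' MI.  Units with `FR_s = 0` or undefined MI are excluded.
#'
#' @param fr_s Synchronized-state rates (Hz).
#' @param mi Modulation indices.
#' @param min_n Minimum usable units.
#' @return A list: `r`, `p_value`, `slope`, `intercept`, `n`.
#' @export
rate_modulation_correlation <- function(fr_s, mi, min_n = 5) {
  keep <- is.finite(fr_s) & fr_s > 0 & is.finite(mi)
  x <- log10(fr_s[keep])
  y <- mi[keep]
  n <- length(x)
  if (n < min_n || sd(x) == 0 || sd(y) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, slope = NA_real_,
                intercept = NA_real_, n = n))
  }
  ct <- cor.test(x, y)
  fit <- lm(y ~ x)
  list(r = unname(ct$estimate), p_value = ct$p.value,
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]), n = n)
}

#' Layer-resolved multiunit modulation index
#'
#' Pools the spikes of all units within each depth window and computes
#' one multiunit modulation index per window for the recording.
#'
#' @param spikes Data frame `unit_id`, `time_s` (all units).
#' @param unit_depths Named numeric vector, depth per unit id.
#' @param seg A `cort_segmentation`.
#' @param depth_windows Named list of depth ranges (micrometers).
#' @return Data frame: `window`, `n_units`, `fr_s`, `fr_d`, `mi`.
#'   Windows containing no units are dropped.
#' @export
mua_modulation <- function(spikes, unit_depths, seg,
                           depth_windows = list(superficial = c(0, 500),
                                                deep = c(800, 1100))) {
  rows <- lapply(names(depth_windows), function(nm) {
    rng <- depth_windows[[nm]]
    ids <- names(unit_depths)[unit_depths >= rng[1] & unit_depths <= rng[2]]
    if (length(ids) == 0) return(NULL)
    pooled <- spikes$time_s[spikes$unit_id %in% ids]
    r <- rate_by_state_spontaneous(pooled, seg)
    data.frame(window = nm, n_units = length(ids), fr_s = r$fr_s,
               fr_d = r$fr_d, mi = modulation_index(r$fr_d, r$fr_s),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(window = character(0), n_units = integer(0),
                                      fr_s = numeric(0), fr_d = numeric(0),
                                      mi = numeric(0))
  out
}

#' One-sample t-test of multiunit modulation across recordings
#'
#' @param mi Numeric vector of per-recording multiunit modulation
#'   indices for one depth window.
#' @return A list: `n`, `mean_mi`, `p_value` (`NA` with fewer than 2
#'   recordings).
#' @export
mua_modulation_test <- function(mi) {
  mi <- mi[is.finite(mi)]
  n <- length(mi)
  if (n < 2) return(list(n = n, mean_mi = if (n) mean(mi) else NA_real_,
                         p_value = NA_real_))
  tt <- t.test(mi, mu = 0)
  list(n = n, mean_mi = mean(mi), p_value = tt$p.value)
}

#' Population summary table by cell class
#'
#' Tabulates, for each of the four classes (superficial/deep x PC/FS),
#' the number of units, the enhanced and suppressed counts
#' (`"enhanced:suppressed"` ratio string), the median modulation index
#' and its signed-rank p-value; and computes the semi-log
#' rate-versus-MI regression within the pooled putative PCs and pooled
#' putative FSs.
#'
#' @param results Data frame with one row per unit: `unit_id`, `fr_s`,
#'   `fr_d`, `mi`, `p_value`, `sig_class`.
#' @param labels Data frame from [classify_unit_table()] (needs
#'   `unit_id`, `putative_class`, `layer`, `included`).
#' @param included_only Restrict to units passing the isolation filter.
#' @return A list of class `"cort_summary"`: `class_table` and
#'   `correlations`.
#' @export
summarize_population <- function(results, labels, included_only = TRUE) {
  d <- merge(results, labels, by = "unit_id")
  if (included_only && "included" %in% names(d)) d <- d[d$included, , drop = FALSE]
  d$class4 <- ifelse(d$layer %in% c("superficial", "deep"),
                     paste0(substr(d$layer, 1, 1), d$putative_class),
                     NA_character_)
  rows <- lapply(.classes4, function(cl) {
    dd <- d[!is.na(d$class4) & d$class4 == cl, ]
    n <- nrow(dd)
    n_enh <- sum(dd$sig_class == "enhanced", na.rm = TRUE)
    n_sup <- sum(dd$sig_class == "suppressed", na.rm = TRUE)
    sr <- if (sum(is.finite(dd$mi)) >= 5) population_signed_rank(dd$mi)
          else list(median_mi = if (n) median(dd$mi, na.rm = TRUE) else NA_real_,
                    p_value = NA_real_)
    data.frame(class = cl, n = n, n_enhanced = n_enh, n_suppressed = n_sup,
               ratio = if (n) sprintf("%d:%d", n_enh, n_sup) else "",
               median_mi = sr$median_mi, signed_rank_p = sr$p_value,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  correlations <- lapply(c(PC = "PC", FS = "FS"), function(pc) {
    dd <- d[!is.na(d$putative_class) & d$putative_class == pc, ]
    rate_modulation_correlation(dd$fr_s, dd$mi)
  })
  structure(list(class_table = tab, correlations = correlations),
            class = "cort_summary")
}

#' Per-unit state modulation analysis for a whole unit table
#'
#' Runs the rate, significance, modulation-index and burst-fraction
#' computations for every unit.
#'
#' @param units A `cort_units` object.
#' @param seg A `cort_segmentation` (spontaneous mode) .
#' @param windows A `cort_stim_windows` (evoked mode).
#' @param mode `"spontaneous"` or `"evoked"`.
#' @param alpha Per-cell significance level.
#' @param burst_window_ms Burst window(s) for [burst_fraction()].
#' @return Data frame with one row per unit.
#' @export
modulation_results <- function(units, seg = NULL, windows = NULL,
                               mode = c("spontaneous", "evoked"),
                               alpha = 0.05, burst_window_ms = 20) {
  mode <- match.arg(mode)
  if (mode == "spontaneous") stopifnot(!is.null(seg)) else stopifnot(!is.null(windows))
  rows <- lapply(units$units$unit_id, function(uid) {
    st <- units$spikes$time_s[units$spikes$unit_id == uid]
    r <- if (mode == "spontaneous") rate_by_state_spontaneous(st, seg)
         else rate_by_state_evoked(st, windows)
    sig <- per_cell_significance(r, alpha = alpha)
    row <- data.frame(unit_id = uid, mode = mode, fr_s = sig$fr_s,
                      fr_d = sig$fr_d, mi = sig$mi, p_value = sig$p_value,
                      sig_class = sig$sig_class,
                      flags = paste(sig$flags, collapse = ";"),
                      stringsAsFactors = FALSE)
    if (mode == "spontaneous" && !is.null(seg)) {
      bf <- burst_fraction(st, seg, window_ms = burst_window_ms[1])
      row$frac_sync <- bf$frac_sync
      row$frac_desync <- bf$frac_desync
    }
    row
  })
  do.call(rbind, rows)
}
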