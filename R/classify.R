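# Unit classification: waveform feature extraction, putative FS/PC
# k-means split, depth estimation from the laminar amplitude profile,
# layer assignment, and the isolation-distance quality filter.

#' Extract the three spike waveform features
#'
#' From a mean waveform on the soma channel: trough-to-peak time (global
#' trough to the following positive peak), half-amplitude width of the
#' trough (with linear interpolation between samples), and the asymmetry
#' index `(aR - aL) / (aR + aL)` of the baseline-to-peak amplitudes
#' before (`aL`) and after (`aR`) the trough.  Baseline is the mean of
#' the first 20% of samples; peaks that do not rise above baseline are
#' clipped to 0 and flagged.
#'
#' @param w Numeric waveform (one channel).
#' @param fs Sampling rate (Hz).
#' @return A list with `trough_to_peak_ms`, `half_width_ms`,
#'   `asymmetry`, `excluded` (TRUE when no positive peak follows the
#'   trough), `reason`, `flags`.
#' @export
extract_waveform_features <- function(w, fs) {
  w <- as.numeric(w)
  n <- length(w)
  stopifnot(n >= 8, fs > 0)
  ti <- which.min(w)
  if ((ti - 1) / fs < 0.5e-3 || (n - ti) / fs < 0.5e-3)
    stop("trough needs at least 0.5 ms of context on both sides")
  base <- mean(w[seq_len(max(1, floor(0.2 * n)))])
  flags <- character(0)

  after <- w[(ti + 1):n]
  aR <- max(after) - base
  if (aR <= 0) {
    return(list(trough_to_peak_ms = NA_real_, half_width_ms = NA_real_,
                asymmetry = NA_real_, excluded = TRUE,
                reason = "no positive peak after trough", flags = flags))
  }
  ttp_ms <- which.max(after) / fs * 1000

  aL <- max(w[seq_len(ti - 1)]) - base
  if (aL < 0) {
    aL <- 0
    flags <- c(flags, "left_peak_clipped")
  }
  asym <- (aR - aL) / (aR + aL)

  depth <- base - w[ti]
  half_level <- base - depth / 2
  left <- rev(which(w[seq_len(ti - 1)] > half_level))
  right <- which(w[(ti + 1):n] > half_level) + ti
  if (length(left) == 0 || length(right) == 0) {
    hw_ms <- NA_real_
    flags <- c(flags, "half_width_unresolved")
  } else {
    j <- left[1]
    xl <- j + (w[j] - half_level) / (w[j] - w[j + 1])
    k <- right[1]
    xr <- k - (w[k] - half_level) / (w[k] - w[k - 1])
    hw_ms <- (xr - xl) / fs * 1000
  }
  list(trough_to_peak_ms = ttp_ms, half_width_ms = hw_ms, asymmetry = asym,
       excluded = FALSE, reason = NA_character_, flags = flags)
}

#' Split units into putative FS and PC classes
#'
#' k-means (k = 2, 50 restarts under a fixed seed) on the z-scored
#' three-feature space; the cluster with the smaller mean
#' trough-to-peak time is labeled FS (narrow spikes).  With fewer than
#' 4 units, or degenerate identical features, all units are labeled PC
#' with a warning.
#'
#' @param features Data frame with columns `trough_to_peak_ms`,
#'   `half_width_ms`, `asymmetry` (one row per unit).
#' @param seed Seed for the k-means restarts.
#' @return Character vector of `"FS"` / `"PC"` labels.
#' @export
classify_units <- function(features, seed = 1) {
  cols <- c("trough_to_peak_ms", "half_width_ms", "asymmetry")
  stopifnot(all(cols %in% names(features)))
  m <- as.matrix(features[, cols])
  n <- nrow(m)
  if (n < 4) {
    warning("insufficient units for clustering; all labeled PC")
    return(rep("PC", n))
  }
  z <- scale(m)
  z[, apply(m, 2, sd) == 0] <- 0
  set.seed(substream_seed(seed, "unit-kmeans"))
  km <- tryCatch(kmeans(z, centers = 2, nstart = 50),
                 error = function(e) NULL)
  if (is.null(km) || length(unique(km$cluster)) < 2) {
    warning("degenerate feature space; all units labeled PC")
    return(rep("PC", n))
  }
  ttp_means <- tapply(m[, "trough_to_peak_ms"], km$cluster, mean)
  fs_cluster <- as.integer(names(which.min(ttp_means)))
  unname(ifelse(km$cluster == fs_cluster, "FS", "PC"))
}

#' Estimate unit depth from the laminar amplitude profile
#'
#' The unit's soma is placed at the channel whose mean waveform has the
#' largest peak-to-trough amplitude; ties go to the shallower channel.
#'
#' @param waveforms Channels x samples matrix of mean waveforms.
#' @param channel_depths_um Channel depths (micrometers), ascending.
#' @return Estimated depth (micrometers), or `NA` when all waveforms
#'   are flat (unit excluded).
#' @export
estimate_depth <- function(waveforms, channel_depths_um) {
  stopifnot(nrow(waveforms) == length(channel_depths_um),
            nrow(waveforms) >= 2,
            !is.unsorted(channel_depths_um))
  amp <- apply(waveforms, 1, function(r) max(r) - min(r))
  if (all(amp == 0)) return(NA_real_)
  channel_depths_um[which.max(amp)]
}

#' Assign a cortical layer from depth
#'
#' Depths of 0-500 micrometers are putative superficial layers (L2/3)
#' and 800-1100 micrometers putative deep layers (L5); boundaries
#' inclusive.  Intermediate or deeper units are left unassigned.
#'
#' @param depth_um Depth(s) below the pia (micrometers).
#' @return Character vector: `"superficial"`, `"deep"` or
#'   `"unassigned"` (`NA` input gives `NA`).
#' @export
assign_layer <- function(depth_um) {
  if (any(depth_um < 0, na.rm = TRUE)) stop("depth must be >= 0")
  out <- rep(NA_character_, length(depth_um))
  ok <- !is.na(depth_um)
  out[ok] <- "unassigned"
  out[ok & depth_um <= 500] <- "superficial"
  out[ok & depth_um >= 800 & depth_um <= 1100] <- "deep"
  out
}

#' Isolation distance of a sorted cluster
#'
#' Squared Mahalanobis distance — with respect to the cluster's own
#' covariance, centered at the cluster centroid — of the n-th closest
#' non-member point, where n is the cluster size.  When fewer
#' non-members than members exist the distance is `Inf`.  A singular
#' covariance is regularized with a `1e-6 * trace` ridge and flagged.
#'
#' @param cluster_points Numeric matrix (points x features) of cluster
#'   member feature vectors.
#' @param other_points Numeric matrix of all non-member feature vectors.
#' @return Numeric isolation distance with attribute
#'   `"ridge_regularized"`.
#' @export
isolation_distance <- function(cluster_points, other_points) {
  cluster_points <- as.matrix(cluster_points)
  other_points <- as.matrix(other_points)
  n <- nrow(cluster_points)
  d <- ncol(cluster_points)
  stopifnot(n > d, nrow(other_points) > 0, ncol(other_points) == d)
  if (nrow(other_points) < n) {
    out <- Inf
    attr(out, "ridge_regularized") <- FALSE
    return(out)
  }
  s <- cov(cluster_points)
  ridge <- FALSE
  if (!is.finite(rcond_safe(s)) || rcond_safe(s) < 1e-12) {
    s <- s + diag(1e-6 * sum(diag(s)) + 1e-12, d)
    ridge <- TRUE
    warning("singular cluster covariance; ridge-regularized")
  }
  d2 <- mahalanobis(other_points, colMeans(cluster_points), s)
  out <- sort(d2)[n]
  attr(out, "ridge_regularized") <- ridge
  out
}

rcond_safe <- function(s) {
  tryCatch(rcond(s), error = function(e) 0)
}

#' Classify and label every unit of a unit table
#'
#' Full per-unit labeling stage: depth from the amplitude profile,
#' waveform features on the soma channel, FS/PC k-means split, layer
#' assignment, and the isolation-distance inclusion filter
#' (`isolation_distance >= 20`).
#'
#' @param units A `cort_units` object (with waveforms).
#' @param seed Seed for the k-means restarts.
#' @param min_isolation Inclusion threshold on isolation distance.
#' @return Data frame with one row per unit: `unit_id`,
#'   `putative_class`, `depth_um`, `layer`, `trough_to_peak_ms`,
#'   `half_width_ms`, `asymmetry`, `isolation_distance`, `included`,
#'   `exclude_reason`.
#' @export
classify_unit_table <- function(units, seed = 1, min_isolation = 20) {
  stopifnot(inherits(units, "cort_units"), !is.null(units$waveforms))
  tab <- units$units
  n <- nrow(tab)
  depths <- rep(NA_real_, n)
  feats <- data.frame(trough_to_peak_ms = rep(NA_real_, n),
                      half_width_ms = NA_real_, asymmetry = NA_real_)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    wf <- units$waveforms[[tab$unit_id[i]]]
    depths[i] <- estimate_depth(wf, units$channel_depths_um)
    if (is.na(depths[i])) {
      reason[i] <- "flat waveform"
      next
    }
    soma <- which(units$channel_depths_um == depths[i])[1]
    f <- tryCatch(extract_waveform_features(wf[soma, ], units$waveform_fs),
                  error = function(e)
                    list(excluded = TRUE, reason = conditionMessage(e)))
    if (f$excluded) {
      reason[i] <- f$reason
      next
    }
    feats[i, ] <- f[c("trough_to_peak_ms", "half_width_ms", "asymmetry")]
  }
  usable <- !is.na(feats$trough_to_peak_ms)
  putative <- rep(NA_character_, n)
  if (any(usable)) putative[usable] <- classify_units(feats[usable, ], seed = seed)
  out <- data.frame(unit_id = tab$unit_id,
                    putative_class = putative,
                    depth_um = depths,
                    layer = assign_layer(depths),
                    stringsAsFactors = FALSE)
  out <- cbind(out, feats)
  out$isolation_distance <- tab$isolation_distance
  out$included <- usable & out$isolation_distance >= min_isolation
  out$exclude_reason <- reason
  out$exclude_reason[usable & !out$included] <- "isolation distance below threshold"
  out
}
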