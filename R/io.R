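# On-disk formats: LFP as flat little-endian float32 binary (channel-major
# frames) with a JSON sidecar; spikes, unit tables, waveforms and state
# labels as delimited text; ground truth and manifests as JSON.

#' Write a recording to disk
#'
#' Writes `<prefix>.bin` (float32 little-endian, one frame = all
#' channels) and `<prefix>.json` (sampling rate, channel count and
#' depths, units, stimulation times).
#'
#' @param rec A `cort_recording`.
#' @param prefix Output path prefix (no extension).
#' @return The two file paths, invisibly.
#' @export
write_recording <- function(rec, prefix) {
  stopifnot(inherits(rec, "cort_recording"))
  bin_path <- paste0(prefix, ".bin")
  meta_path <- paste0(prefix, ".json")
  con <- file(bin_path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(rec$lfp)), con, size = 4, endian = "little")
  meta <- list(fs = rec$fs,
               n_channels = ncol(rec$lfp),
               n_frames = nrow(rec$lfp),
               channel_depths_um = rec$channel_depths_um,
               units = "uV",
               stim_times = rec$stim_times)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(bin = bin_path, meta = meta_path))
}

#' Read a recording written by [write_recording()]
#'
#' @param prefix Path prefix (no extension).
#' @return A `cort_recording`.
#' @export
read_recording <- function(prefix) {
  bin_path <- paste0(prefix, ".bin")
  meta_path <- paste0(prefix, ".json")
  if (!file.exists(bin_path) || !file.exists(meta_path))
    stop("missing recording file(s) at prefix ", prefix)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (f in c("fs", "n_channels", "n_frames", "channel_depths_um"))
    if (is.null(meta[[f]])) stop("recording sidecar missing field '", f, "'")
  expected <- 4 * meta$n_frames * meta$n_channels
  actual <- file.info(bin_path)$size
  if (actual != expected)
    stop("recording size mismatch: sidecar implies ", expected,
         " bytes but file has ", actual)
  if (is.unsorted(meta$channel_depths_um, strictly = TRUE))
    stop("channel_depths_um must be strictly increasing")
  con <- file(bin_path, "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = meta$n_frames * meta$n_channels,
               size = 4, endian = "little")
  lfp <- matrix(x, nrow = meta$n_frames, ncol = meta$n_channels, byrow = TRUE)
  structure(list(lfp = lfp, fs = meta$fs,
                 channel_depths_um = meta$channel_depths_um,
                 stim_times = meta$stim_times),
            class = "cort_recording")
}

#' Write/read a unit table
#'
#' `units.csv` holds the per-unit metadata, `spikes.csv` the
#' `(unit_id, time_s)` table, `units.json` the waveform sampling rate
#' and channel depths, and `waveforms/<unit_id>.csv` one channels x
#' samples matrix per unit.
#'
#' @param units A `cort_units` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_unit_table <- function(units, dir) {
  stopifnot(inherits(units, "cort_units"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(units$units, file.path(dir, "units.csv"), row.names = FALSE)
  write.csv(units$spikes, file.path(dir, "spikes.csv"), row.names = FALSE)
  jsonlite::write_json(list(waveform_fs = units$waveform_fs,
                            channel_depths_um = units$channel_depths_um),
                       file.path(dir, "units.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(units$waveforms)) {
    wdir <- file.path(dir, "waveforms")
    dir.create(wdir, showWarnings = FALSE)
    for (uid in names(units$waveforms))
      utils::write.table(units$waveforms[[uid]],
                         file.path(wdir, paste0(uid, ".csv")),
                         sep = ",", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_unit_table
#' @export
read_unit_table <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "units.json"), simplifyVector = TRUE)
  tab <- read.csv(file.path(dir, "units.csv"), stringsAsFactors = FALSE)
  spikes <- read.csv(file.path(dir, "spikes.csv"), stringsAsFactors = FALSE)
  wdir <- file.path(dir, "waveforms")
  wf <- NULL
  if (dir.exists(wdir)) {
    wf <- lapply(tab$unit_id, function(uid)
      as.matrix(read.csv(file.path(wdir, paste0(uid, ".csv")), header = FALSE)))
    names(wf) <- tab$unit_id
  }
  structure(list(units = tab, spikes = spikes, waveforms = wf,
                 waveform_fs = meta$waveform_fs,
                 channel_depths_um = meta$channel_depths_um),
            class = "cort_units")
}

#' Write a segmentation as delimited text + JSON epochs
#'
#' @param seg A `cort_segmentation`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_segmentation <- function(seg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(data.frame(bin_start_s = (seq_len(seg$n_bins) - 1) * seg$bin_s,
                       label = seg$bin_labels),
            file.path(dir, "state_labels.csv"), row.names = FALSE)
  jsonlite::write_json(seg$epochs, file.path(dir, "epochs.json"), digits = NA)
  if (!is.null(seg$updown))
    write.csv(data.frame(bin_start_s = (seq_along(seg$updown$labels) - 1) *
                           seg$updown$bin_s,
                         label = seg$updown$labels),
              file.path(dir, "updown_labels.csv"), row.names = FALSE)
  invisible(dir)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Generate a complete synthetic dataset on disk
#'
#' Runs [simulate_recording()] and writes every component: the LFP
#' recording, the unit table with waveforms, the ground-truth state and
#' up/down labels, and a manifest with the config hash and per-file
#' checksums.  Identical configuration and seed reproduce bit-identical
#' files.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with `paths`, `manifest` and the in-memory
#'   `sim` bundle.
#' @export
generate_dataset <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, 2) != 0) stop("output path not writable: ", out_dir)
  sim <- simulate_recording(cfg)
  write_recording(sim$recording, file.path(out_dir, "recording"))
  write_unit_table(sim$units, out_dir)
  write.csv(data.frame(bin_start_s = seq_along(sim$states$bin_labels) - 1,
                       label = sim$states$bin_labels),
            file.path(out_dir, "truth_states.csv"), row.names = FALSE)
  write.csv(data.frame(bin_start_s = (seq_along(sim$updown) - 1) *
                         attr(sim$updown, "bin_s"),
                       label = as.character(sim$updown)),
            file.path(out_dir, "truth_updown.csv"), row.names = FALSE)
  jsonlite::write_json(sim$states$epochs, file.path(out_dir, "truth_epochs.json"),
                       digits = NA)
  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(config_hash = config_hash(cfg),
                   tool_version = as.character(utils::packageVersion("cortstate")),
                   seed = cfg$seed,
                   checksums = as.list(stats::setNames(unname(sums), files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(paths = file.path(out_dir, files), manifest = manifest,
                 sim = sim))
}
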