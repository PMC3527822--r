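# End-to-end pipeline: simulate -> segment -> classify -> modulate ->
# report, with a manifest recording configuration hash, stage warnings
# and output checksums.

#' Run the full analysis pipeline on a simulated recording
#'
#' Executes every stage in order: dataset generation, low-frequency
#' power and state segmentation, up/down detection, unit classification
#' (features, FS/PC split, depth, layer, isolation filter), per-unit
#' state-modulation statistics, population summary, layer-resolved
#' multiunit modulation, and the text/JSON report.  All stage warnings
#' are collected into the manifest.
#'
#' @param cfg A [sim_config()].  Evoked mode requires `cfg$stim_times`.
#' @param out_dir Output directory.
#' @param mode `"spontaneous"` or `"evoked"`.
#' @param alpha Per-cell significance level.
#' @param lfp_channel Channel for the state-evaluation power series
#'   (default: first channel of the deepest third of the probe).
#' @param burst_window_ms Burst window (ms).
#' @return Invisibly, a list with `manifest`, `seg`, `labels`,
#'   `results`, `summary`, `mua`, `report`.
#' @export
run_pipeline <- function(cfg, out_dir, mode = c("spontaneous", "evoked"),
                         alpha = 0.05, lfp_channel = NULL,
                         burst_window_ms = 20) {
  mode <- match.arg(mode)
  validate_sim_config(cfg)
  if (mode == "evoked" && is.null(cfg$stim_times))
    stop("evoked mode requires stim_times in the configuration")
  warnings_log <- character(0)
  stage <- function(name, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)),
      warning = function(w) {
        warnings_log <<- c(warnings_log, paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }

  ds <- stage("simulate", generate_dataset(cfg, out_dir))
  sim <- ds$sim

  ps <- stage("power", compute_low_freq_power(sim$recording, channel = lfp_channel))
  seg <- stage("segment", classify_states(ps))
  seg$updown <- stage("updown", detect_updown(sim$units, seg))
  stage("segment-io", write_segmentation(seg, file.path(out_dir, "segmentation")))

  labels <- stage("classify", classify_unit_table(sim$units, seed = cfg$seed))
  write.csv(labels, file.path(out_dir, "unit_labels.csv"), row.names = FALSE)

  windows <- NULL
  if (mode == "evoked")
    windows <- stage("stim-windows",
                     build_stim_windows(cfg$stim_times, cfg$stim_duration_s, ps))
  included <- sim$units
  keep <- labels$included
  included$units <- included$units[keep, , drop = FALSE]
  results <- stage("modulate",
                   modulation_results(included, seg = seg, windows = windows,
                                      mode = mode, alpha = alpha,
                                      burst_window_ms = burst_window_ms))
  write.csv(results, file.path(out_dir, "modulation_results.csv"),
            row.names = FALSE)

  summary <- stage("summarize", summarize_population(results, labels))
  depths <- stats::setNames(labels$depth_um, labels$unit_id)
  mua <- stage("mua", mua_modulation(sim$units$spikes, depths, seg))

  report <- stage("report", render_report(summary, mua = mua,
                                          path = file.path(out_dir, "report")))

  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(config_hash = config_hash(cfg),
                   tool_version = as.character(utils::packageVersion("cortstate")),
                   seed = cfg$seed, mode = mode,
                   warnings = unique(warnings_log),
                   checksums = as.list(stats::setNames(unname(sums), files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, seg = seg, labels = labels,
                 results = results, summary = summary, mua = mua,
                 report = report))
}

fmt6 <- function(x) {
  ifelse(is.na(x), "NA", formatC(signif(x, 6), format = "g", digits = 6))
}

#' Render the population report as text and JSON
#'
#' Emits a table of per-class rows (n, enhanced:suppressed ratio,
#' median modulation index, signed-rank p), the rate-versus-MI
#' correlation block, the multiunit modulation block and, when
#' provided, the burst block.  Numbers are fixed to 6 significant
#' digits in the text rendering; the JSON rendering carries the same
#' values.
#'
#' @param summary A `cort_summary` from [summarize_population()].
#' @param mua Optional [mua_modulation()] data frame.
#' @param bursts Optional [burst_state_comparison()] result.
#' @param path Optional output path prefix; writes `<path>.txt` and
#'   `<path>.json`.
#' @return A list with `text` (character lines) and `json` (string).
#' @export
render_report <- function(summary, mua = NULL, bursts = NULL, path = NULL) {
  stopifnot(inherits(summary, "cort_summary"))
  tab <- summary$class_table
  lines <- c("State-dependent spontaneous firing summary",
             "cell_class  n  enhanced:suppressed  median_MI  signed_rank_p")
  for (i in seq_len(nrow(tab))) {
    lines <- c(lines, sprintf("%-5s %4d  %-10s %10s %12s",
                              tab$class[i], tab$n[i],
                              ifelse(tab$ratio[i] == "", "-", tab$ratio[i]),
                              fmt6(tab$median_mi[i]),
                              fmt6(tab$signed_rank_p[i])))
  }
  lines <- c(lines, "", "Baseline rate vs modulation (semi-log):")
  for (nm in names(summary$correlations)) {
    co <- summary$correlations[[nm]]
    lines <- c(lines, sprintf("  %s: r = %s, p = %s, slope = %s, n = %d",
                              nm, fmt6(co$r), fmt6(co$p_value),
                              fmt6(co$slope), co$n))
  }
  if (!is.null(mua) && nrow(mua) > 0) {
    lines <- c(lines, "", "Multiunit modulation by depth window:")
    for (i in seq_len(nrow(mua)))
      lines <- c(lines, sprintf("  %s: MI = %s (n_units = %d)",
                                mua$window[i], fmt6(mua$mi[i]), mua$n_units[i]))
  }
  if (!is.null(bursts)) {
    lines <- c(lines, "",
               sprintf("Burst fractions: Kruskal-Wallis p = %s",
                       fmt6(bursts$kruskal_p)))
    ct <- bursts$class_tests
    for (i in seq_len(nrow(ct)))
      lines <- c(lines, sprintf("  %s: rank-sum p = %s (n = %d)",
                                ct$class[i], fmt6(ct$p_value[i]), ct$n[i]))
  }
  payload <- list(class_table = tab, correlations = summary$correlations)
  if (!is.null(mua)) payload$mua <- mua
  if (!is.null(bursts)) payload$bursts <- bursts
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, na = "null")
  if (!is.null(path)) {
    writeLines(lines, paste0(path, ".txt"))
    writeLines(json, paste0(path, ".json"))
  }
  list(text = lines, json = json)
}
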