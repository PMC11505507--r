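#' Write / read a gait recording
#'
#' CSV schema: `t,<20 channel names>,activity,label`, one row per sample,
#' `t` a 0-based integer sample index. A sidecar JSON (`<path>.json`) carries
#' the sampling rate, seed and simulation configuration. Values round-trip
#' losslessly at single precision (the CSV writer emits shortest
#' round-trip decimal representations).
#'
#' @param recording a `gait_recording`.
#' @param path CSV path; the sidecar is written next to it.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns the restored `gait_recording`.
#' @export
write_recording <- function(recording, path) {
  readr::write_csv(as.data.frame(recording), path)
  cfg <- attr(recording, "sim_config")
  cfg_json <- NULL
  if (!is.null(cfg)) {
    # named vectors must become JSON objects, not bare arrays
    cfg_json <- lapply(unclass(cfg), function(x) {
      if (is.numeric(x) && !is.null(names(x))) as.list(x) else x
    })
  }
  sidecar <- list(sampling_rate_hz = sampling_rate(recording),
                  seed = if (!is.null(cfg)) cfg$seed else NULL,
                  sim_config = cfg_json)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  ch <- channel_groups()$channel
  missing_ch <- setdiff(c("t", ch, "activity", "label"), names(df))
  if (length(missing_ch) > 0)
    abort(paste0("Recording CSV is missing column(s): ",
                 paste(missing_ch, collapse = ", ")))
  if (!all(df$label %in% 0:1))
    abort("`label` must be 0/1.")
  sig <- as.matrix(df[, ch])
  if (!all(is.finite(sig)))
    abort("Recording contains non-finite signal values.")
  if (!all((df$label == 1L) == (df$activity == "fog")))
    abort("`label` must be 1 exactly where `activity` is 'fog'.")

  sidecar_path <- paste0(path, ".json")
  fs <- 40
  cfg <- NULL
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::fromJSON(sidecar_path, simplifyVector = TRUE)
    if (!is.null(sc$sampling_rate_hz)) fs <- sc$sampling_rate_hz
    if (!is.null(sc$sim_config)) {
      scc <- sc$sim_config
      cfg <- sim_config(
        duration_s = scc$duration_s, sampling_rate_hz = scc$sampling_rate_hz,
        fog_prevalence = scc$fog_prevalence,
        n_fog_episodes = scc$n_fog_episodes,
        fog_duration_s_range = unlist(scc$fog_duration_s_range),
        activity_mix = unlist(scc$activity_mix),
        noise_sd = unlist(scc$noise_sd), seed = scc$seed)
    }
  }
  rec <- tibble::as_tibble(df)
  rec$t <- as.integer(rec$t)
  rec$label <- as.integer(rec$label)
  rec[ch] <- as_float32(sig)
  structure(rec, class = c("gait_recording", class(tibble::tibble()))) |>
    set_recording_attrs(sampling_rate_hz = fs, sim_config = cfg)
}

#' Write a detection trace and its cue command log
#'
#' The trace goes to CSV (`t,score,detected,fog_condition,cue_active`); the
#' cue on/off events are appended as JSON lines to `<path>_events.jsonl`,
#' standing in for the RF commands sent to the actuators.
#'
#' @param trace a `detection_trace`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  readr::write_csv(as.data.frame(trace), path)
  events <- cue_events(trace)
  ev_path <- sub("\\.csv$", "", path)
  ev_path <- paste0(ev_path, "_events.jsonl")
  lines <- purrr::pmap_chr(events, function(t, event, intensity) {
    jsonlite::toJSON(list(t = t, event = event, intensity = intensity),
                     auto_unbox = TRUE)
  })
  writeLines(lines, ev_path)
  invisible(path)
}
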