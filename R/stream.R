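#' Streaming detector configuration
#'
#' @param threshold detection threshold on the model score, strict
#'   (`score > threshold` detects). 0.9 is the deployment default; per-patient
#'   values of 0.2-0.4 were used in the real-time sessions the package
#'   emulates.
#' @param cue_duration_s seconds of cueing after the last detected sample;
#'   the cue countdown loses one unit per second, so `fog_condition_max`
#'   must equal `cue_duration_s`.
#' @param sampling_rate_hz nominal 40 Hz.
#' @param fog_condition_max initial value of the cue countdown on detection.
#' @param stim_intensity_level vibration intensity 1-10 (logged metadata
#'   only; no actuator exists here).
#' @return A `detector_config` list.
#' @export
detector_config <- function(threshold = 0.9, cue_duration_s = 3,
                            sampling_rate_hz = 40, fog_condition_max = 3L,
                            stim_intensity_level = 5L) {
  if (threshold <= 0 || threshold >= 1)
    abort("`threshold` must lie strictly between 0 and 1.")
  if (!isTRUE(all.equal(cue_duration_s, fog_condition_max)))
    abort("`fog_condition_max` must equal `cue_duration_s` (one unit per second).")
  stopifnot(sampling_rate_hz > 0,
            stim_intensity_level >= 1, stim_intensity_level <= 10)
  structure(
    list(threshold = threshold, cue_duration_s = cue_duration_s,
         sampling_rate_hz = sampling_rate_hz,
         fog_condition_max = as.integer(fog_condition_max),
         stim_intensity_level = as.integer(stim_intensity_level)),
    class = "detector_config"
  )
}

#' Threshold function on the model score
#'
#' Detection is strict: a score equal to the threshold does not trigger
#' ("exceeds" is read literally).
#'
#' @param score model score(s) in [0, 1].
#' @param threshold detection threshold.
#' @return integer 0/1 vector.
#' @export
threshold_fn <- function(score, threshold = 0.9) {
  stopifnot(all(score >= 0 & score <= 1))
  as.integer(score > threshold)
}

#' Advance the FoG_condition cue countdown by one sample
#'
#' On detection the countdown is set to `max_state` (3 by default) and its
#' one-second decrement timer restarts; without detection it loses one unit
#' every `fs` samples, with a floor at 0. The cue is active while the
#' countdown exceeds 0, so an isolated detection keeps the cue on for exactly
#' `max_state * fs` samples (120 at 40 Hz, i.e. 3 s).
#'
#' @param state current countdown value, 0 to `max_state`.
#' @param detected 0/1 detection at this sample.
#' @param samples_since_detection samples elapsed since the last detection
#'   (before this sample).
#' @param fs sampling rate in samples per second.
#' @param max_state countdown start value.
#' @return list with updated `state` and `samples_since_detection`.
#' @export
update_fog_condition <- function(state, detected, samples_since_detection,
                                 fs = 40L, max_state = 3L) {
  stopifnot(state >= 0, state <= max_state)
  if (detected == 1L)
    return(list(state = as.integer(max_state), samples_since_detection = 0L))
  since <- samples_since_detection + 1L
  if (state > 0L && since %% fs == 0L) state <- state - 1L
  list(state = as.integer(state), samples_since_detection = since)
}

#' Run the online detection loop over a recording
#'
#' Emulates the 40 Hz real-time loop: each sample is pushed into the rolling
#' buffer; once the buffer is warm a window is emitted, scored by the model,
#' thresholded, and fed to the cue countdown. During warm-up the score is 0
#' and nothing is detected. Streamed scores are bit-identical to batch
#' prediction over [batch_windows()] because both run the same sequential
#' single-precision forward pass on identical windows.
#'
#' @param recording a `gait_recording` with the model's channel set.
#' @param model a `fog_model`, or a stub function `f(window, t)` returning a
#'   score in [0, 1] (handy for testing the state machine in isolation).
#' @param config a [detector_config()].
#' @param channels channel columns the model was trained on.
#' @return A `detection_trace` tibble with per-sample columns `t` (0-based),
#'   `score`, `detected`, `fog_condition` and `cue_active`, plus an `events`
#'   attribute logging cue on/off commands (the stand-in for the RF command
#'   to the vibration actuators).
#' @export
run_stream <- function(recording, model, config = detector_config(),
                       channels = channel_groups()$channel) {
  is_stub <- is.function(model)
  if (!is_stub) stopifnot(inherits(model, "fog_model"))
  use_ch <- intersect(channels, names(recording))
  if (!is_stub && length(use_ch) != model$config$n_channels)
    abort(sprintf("Recording provides %d model channels but the model expects %d.",
                  length(use_ch), model$config$n_channels))
  S <- signal_matrix(recording, use_ch)
  T_n <- nrow(S)
  ps <- if (is_stub) 0L else model$config$ps
  if (T_n <= ps) abort("Recording shorter than the model's warm-up window.")

  # streaming preprocessing: rolling buffer, one push per sample
  buf <- rolling_buffer(ps, length(use_ch))
  W <- matrix(0, T_n - ps, length(use_ch) * (ps + 1L))
  k <- 0L
  for (t in seq_len(T_n)) {
    pushed <- push_sample(buf, S[t, ])
    buf <- pushed$buffer
    if (!is.null(pushed$window)) {
      k <- k + 1L
      W[k, ] <- pushed$window
    }
  }

  scores <- numeric(T_n)
  if (is_stub) {
    for (t in seq_len(T_n)) scores[t] <- model(W[t, ], t - 1L)
  } else {
    scores[(ps + 1L):T_n] <- predict(model, W)
  }

  detected <- integer(T_n)
  detected[(ps + 1L):T_n] <- threshold_fn(scores[(ps + 1L):T_n],
                                          config$threshold)

  fs <- as.integer(config$sampling_rate_hz)
  fog_condition <- integer(T_n)
  state <- 0L
  since <- 0L
  for (t in seq_len(T_n)) {
    upd <- update_fog_condition(state, detected[t], since, fs,
                                config$fog_condition_max)
    state <- upd$state
    since <- upd$samples_since_detection
    fog_condition[t] <- state
  }
  cue_active <- as.integer(fog_condition > 0L)

  edges <- diff(c(0L, cue_active))
  events <- tibble::tibble(
    t = (which(edges != 0L)) - 1L,
    event = ifelse(edges[edges != 0L] > 0L, "cue_on", "cue_off"),
    intensity = ifelse(edges[edges != 0L] > 0L,
                       config$stim_intensity_level, 0L)
  )

  trace <- tibble::tibble(t = 0:(T_n - 1L), score = scores,
                          detected = detected,
                          fog_condition = fog_condition,
                          cue_active = cue_active)
  structure(trace, class = c("detection_trace", class(tibble::tibble())),
            events = events, threshold = config$threshold,
            sampling_rate_hz = config$sampling_rate_hz)
}

#' Cue command log of a detection trace
#' @param trace a `detection_trace`.
#' @return tibble of cue on/off events with 0-based sample times.
#' @export
cue_events <- function(trace) attr(trace, "events")
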