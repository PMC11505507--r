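#' Channel layout of the simulated gait recorder
#'
#' The wearable records 20 signals at 40 Hz from four sensor groups: two
#' tri-axial accelerometers (`ACC`, 6 channels), two tri-axial gyroscopes
#' (`GYRO`, 6), four complementary-filter angle estimates (`CF`, 4) and four
#' muscle-activity channels (`MA`, 4).
#'
#' @return A tibble with columns `channel` and `group`.
#' @export
channel_groups <- function() {
  tibble::tibble(
    channel = c(
      paste0("acc1_", c("x", "y", "z")), paste0("acc2_", c("x", "y", "z")),
      paste0("gyro1_", c("x", "y", "z")), paste0("gyro2_", c("x", "y", "z")),
      paste0("cf", 1:2, "_pitch"), paste0("cf", 1:2, "_roll"),
      paste0("ma", 1:4)
    ),
    group = c(rep("ACC", 6), rep("GYRO", 6), rep("CF", 4), rep("MA", 4))
  )
}

#' Simulation configuration for synthetic gait recordings
#'
#' Defaults describe a typical recording session of the cohort the package
#' emulates: several-minute recordings at 40 Hz, FoG making up a few percent
#' of samples (cohort average 5.9%, range 1.5-15.4%), and a handful to a few
#' dozen discrete FoG episodes interleaved with walking, standing and turning.
#'
#' @param duration_s recording length in seconds.
#' @param sampling_rate_hz sampling rate; the recorder runs at 40 Hz.
#' @param fog_prevalence target fraction of samples labeled FoG, in [0, 0.5].
#' @param n_fog_episodes number of discrete FoG episodes. When both prevalence
#'   and episode count are given, episode durations are rescaled so the count
#'   wins and the total FoG share matches the prevalence.
#' @param fog_duration_s_range min/max seconds for a FoG episode before
#'   rescaling.
#' @param activity_mix named proportions over walk/stand/turn for the non-FoG
#'   time; must sum to 1.
#' @param noise_sd per-group Gaussian noise standard deviations, named
#'   `acc`, `gyro`, `cf`, `ma` (sensor-like arbitrary units).
#' @param seed integer seed; recordings are byte-identical given the same
#'   configuration.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(duration_s = 300,
                       sampling_rate_hz = 40,
                       fog_prevalence = 0.059,
                       n_fog_episodes = 10,
                       fog_duration_s_range = c(2, 8),
                       activity_mix = c(walk = 0.6, stand = 0.25, turn = 0.15),
                       noise_sd = c(acc = 0.05, gyro = 0.05, cf = 0.02, ma = 0.05),
                       seed = 1L) {
  cfg <- list(
    duration_s = duration_s, sampling_rate_hz = sampling_rate_hz,
    n_channels = 20L, fog_prevalence = fog_prevalence,
    n_fog_episodes = as.integer(n_fog_episodes),
    fog_duration_s_range = fog_duration_s_range,
    activity_mix = activity_mix, noise_sd = noise_sd, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    is.numeric(cfg$duration_s), cfg$duration_s > 0,
    is.numeric(cfg$sampling_rate_hz), cfg$sampling_rate_hz > 0,
    length(cfg$fog_duration_s_range) == 2,
    all(cfg$fog_duration_s_range > 0),
    cfg$n_fog_episodes >= 0
  )
  if (cfg$fog_prevalence < 0 || cfg$fog_prevalence > 0.5)
    abort("`fog_prevalence` must lie in [0, 0.5].",
          class = "fogcue_config_error")
  if (cfg$fog_duration_s_range[1] > cfg$fog_duration_s_range[2])
    abort("`fog_duration_s_range` must satisfy min <= max.",
          class = "fogcue_config_error")
  if (abs(sum(cfg$activity_mix) - 1) > 1e-9)
    abort("`activity_mix` proportions must sum to 1.",
          class = "fogcue_config_error")
  if (!all(c("walk", "stand", "turn") %in% names(cfg$activity_mix)))
    abort("`activity_mix` needs named walk/stand/turn entries.",
          class = "fogcue_config_error")
  if (!all(c("acc", "gyro", "cf", "ma") %in% names(cfg$noise_sd)) ||
      any(cfg$noise_sd <= 0))
    abort("`noise_sd` needs positive acc/gyro/cf/ma entries.",
          class = "fogcue_config_error")
  invisible(cfg)
}

#' Lay out walking, standing, turning and FoG episodes over a recording
#'
#' Tiles `[0, T)` (sample indices, 0-based, half-open) with activity episodes.
#' Exactly `n_fog_episodes` FoG episodes are placed, separated by at least one
#' second of non-FoG activity; their durations are drawn uniformly from
#' `fog_duration_s_range` and then rescaled so the total FoG share matches
#' `fog_prevalence` (the episode count wins when the two conflict).
#'
#' @param config a [sim_config()].
#' @return A tibble of episodes with columns `start`, `end` (0-based sample
#'   indices, half-open) and `kind` in walk/stand/turn/fog.
#' @export
make_activity_schedule <- function(config) {
  validate_sim_config(config)
  fs <- config$sampling_rate_hz
  T_n <- as.integer(round(config$duration_s * fs))
  n_fog <- config$n_fog_episodes
  min_gap <- as.integer(round(fs)) # >= 1 s of non-fog between fog episodes

  fog_total <- if (n_fog > 0) as.integer(round(config$fog_prevalence * T_n)) else 0L
  if (n_fog > 0) {
    if (n_fog * mean(config$fog_duration_s_range) > config$duration_s)
      abort("Infeasible configuration: requested FoG episodes cannot fit the recording duration.",
            class = "fogcue_config_error")
    if (fog_total + (n_fog + 1L) * min_gap > T_n)
      abort("Infeasible configuration: FoG demand plus inter-episode gaps exceeds the recording.",
            class = "fogcue_config_error")
    if (fog_total < n_fog)
      abort("Infeasible configuration: prevalence too small for the requested episode count.",
            class = "fogcue_config_error")
  }

  withr::with_seed(config$seed, {
    if (n_fog > 0) {
      durs <- runif(n_fog, config$fog_duration_s_range[1],
                    config$fog_duration_s_range[2])
      fog_len <- round_preserving_sum(durs / sum(durs) * fog_total)
      fog_len <- pmax(fog_len, 1L)
      # re-balance after the floor so the total is exact
      excess <- sum(fog_len) - fog_total
      i <- 1L
      while (excess > 0L) {
        j <- which.max(fog_len)
        fog_len[j] <- fog_len[j] - 1L
        excess <- excess - 1L
        i <- i + 1L
      }
    } else {
      fog_len <- integer(0)
    }

    non_fog_total <- T_n - sum(fog_len)
    n_gaps <- n_fog + 1L
    w <- runif(n_gaps, 0.5, 1.5)
    spare <- non_fog_total - n_gaps * min_gap
    gap_len <- min_gap + round_preserving_sum(w / sum(w) * spare)

    kinds <- character(0); lens <- integer(0)
    for (g in seq_len(n_gaps)) {
      remaining <- gap_len[g]
      while (remaining > 0L) {
        len <- as.integer(round(runif(1, 2, 8) * fs))
        if (remaining - len < min_gap) len <- remaining
        kind <- sample(c("walk", "stand", "turn"), 1,
                       prob = config$activity_mix[c("walk", "stand", "turn")])
        kinds <- c(kinds, kind); lens <- c(lens, len)
        remaining <- remaining - len
      }
      if (g <= n_fog) {
        kinds <- c(kinds, "fog"); lens <- c(lens, fog_len[g])
      }
    }
  })

  ends <- cumsum(as.numeric(lens))
  tibble::tibble(
    start = as.integer(c(0, head(ends, -1))),
    end = as.integer(ends),
    kind = kinds
  )
}

round_preserving_sum <- function(x) {
  total <- round(sum(x))
  fl <- floor(x)
  resid <- as.integer(total - sum(fl))
  out <- as.integer(fl)
  if (resid > 0) {
    up <- order(x - fl, decreasing = TRUE)[seq_len(resid)]
    out[up] <- out[up] + 1L
  }
  out
}

#' Synthesize 20-channel sensor signals for an activity schedule
#'
#' Generative models per activity (documented surrogates, not measured
#' patient morphology):
#' * walk: 1 Hz gait fundamental plus 2nd and 3rd harmonics with per-channel
#'   amplitudes/phases on accelerometer and gyroscope channels, a small 1 Hz
#'   sway on angle channels, plus Gaussian noise;
#' * stand: noise only;
#' * turn: walk plus a slow 0.1-0.3 Hz offset drift on gyroscope and angle
#'   channels;
#' * fog: locomotor band suppressed (x0.15) and a low-amplitude 3-8 Hz
#'   trembling band added on accelerometer/gyroscope channels;
#'   muscle-activity channels elevated in variance.
#'
#' @param schedule episode tibble from [make_activity_schedule()].
#' @param config the matching [sim_config()].
#' @return A `gait_recording` tibble (see [generate_recording()]).
#' @export
synthesize_channels <- function(schedule, config) {
  validate_sim_config(config)
  fs <- config$sampling_rate_hz
  T_n <- max(schedule$end)
  if (min(schedule$start) != 0L || any(schedule$start >= schedule$end))
    abort("`schedule` must tile [0, T) with non-empty episodes.")

  ch <- channel_groups()
  n_ch <- nrow(ch)
  acc_gyro <- ch$group %in% c("ACC", "GYRO")
  cf <- ch$group == "CF"
  ma <- ch$group == "MA"
  sd_of <- c(ACC = unname(config$noise_sd["acc"]),
             GYRO = unname(config$noise_sd["gyro"]),
             CF = unname(config$noise_sd["cf"]),
             MA = unname(config$noise_sd["ma"]))[ch$group]

  signals <- matrix(0, nrow = T_n, ncol = n_ch,
                    dimnames = list(NULL, ch$channel))
  activity <- character(T_n)

  withr::with_seed(config$seed + 1000000L, {
    # person-specific channel parameters, fixed across the recording
    A1 <- runif(n_ch, 0.8, 1.2); A2 <- runif(n_ch, 0.2, 0.4)
    A3 <- runif(n_ch, 0.05, 0.15)
    ph1 <- runif(n_ch, 0, 2 * pi); ph2 <- runif(n_ch, 0, 2 * pi)
    ph3 <- runif(n_ch, 0, 2 * pi)
    cf_amp <- runif(n_ch, 0.1, 0.3)
    drift_f <- runif(n_ch, 0.1, 0.3); drift_A <- runif(n_ch, 0.5, 1.0)
    drift_ph <- runif(n_ch, 0, 2 * pi)

    for (e in seq_len(nrow(schedule))) {
      idx <- (schedule$start[e] + 1L):schedule$end[e]
      tt <- (idx - 1L) / fs
      kind <- schedule$kind[e]
      activity[idx] <- kind
      n_e <- length(idx)

      block <- matrix(rnorm(n_e * n_ch), n_e, n_ch) *
        matrix(sd_of, n_e, n_ch, byrow = TRUE)

      if (kind %in% c("walk", "turn", "fog")) {
        loco_scale <- if (kind == "fog") 0.15 else 1
        for (c_i in which(acc_gyro)) {
          loco <- A1[c_i] * sin(2 * pi * tt + ph1[c_i]) +
            A2[c_i] * sin(4 * pi * tt + ph2[c_i]) +
            A3[c_i] * sin(6 * pi * tt + ph3[c_i])
          block[, c_i] <- block[, c_i] + loco_scale * loco
        }
        for (c_i in which(cf)) {
          block[, c_i] <- block[, c_i] +
            loco_scale * cf_amp[c_i] * sin(2 * pi * tt + ph1[c_i])
        }
        if (kind != "fog") {
          for (c_i in which(ma)) block[, c_i] <- block[, c_i] * 1.5
        }
      }
      if (kind == "turn") {
        for (c_i in which(ch$group %in% c("GYRO", "CF"))) {
          block[, c_i] <- block[, c_i] +
            drift_A[c_i] * sin(2 * pi * drift_f[c_i] * tt + drift_ph[c_i])
        }
      }
      if (kind == "fog") {
        tremor_f <- runif(1, 3.5, 7.5)  # trembling-in-place band, 3-8 Hz
        for (c_i in which(acc_gyro)) {
          tremor_ph <- runif(1, 0, 2 * pi)
          block[, c_i] <- block[, c_i] +
            0.4 * sin(2 * pi * tremor_f * tt + tremor_ph)
        }
        for (c_i in which(ma)) block[, c_i] <- block[, c_i] * 3
      }
      signals[idx, ] <- block
    }
  })

  new_gait_recording(as_float32(signals), activity, config)
}

new_gait_recording <- function(signals, activity, config) {
  label <- as.integer(activity == "fog")
  stopifnot(all(is.finite(signals)), nrow(signals) >= 1)
  rec <- tibble::as_tibble(as.data.frame(signals))
  rec <- dplyr::bind_cols(
    tibble::tibble(t = 0:(nrow(signals) - 1L)), rec,
    tibble::tibble(activity = activity, label = label)
  )
  structure(rec,
            class = c("gait_recording", class(tibble::tibble()))) |>
    set_recording_attrs(sampling_rate_hz = config$sampling_rate_hz,
                        sim_config = config)
}

set_recording_attrs <- function(rec, sampling_rate_hz, sim_config = NULL) {
  attr(rec, "sampling_rate_hz") <- sampling_rate_hz
  attr(rec, "sim_config") <- sim_config
  rec
}

#' Generate a labeled synthetic gait recording
#'
#' Composes [make_activity_schedule()] and [synthesize_channels()]:
#' a fixed-rate, 20-channel signal tibble with per-sample activity and a
#' binary FoG label (`label == 1` exactly where `activity == "fog"`).
#' Deterministic given the configuration, including its seed.
#'
#' @param config a [sim_config()].
#' @return A `gait_recording`: tibble with columns `t` (0-based sample
#'   index), the 20 channels of [channel_groups()], `activity` and `label`;
#'   attributes `sampling_rate_hz` and `sim_config`.
#' @export
generate_recording <- function(config = sim_config()) {
  schedule <- make_activity_schedule(config)
  synthesize_channels(schedule, config)
}

#' Extract the T x 20 signal matrix from a recording
#'
#' @param recording a `gait_recording` (or any tibble with the 20 channel
#'   columns).
#' @param channels channel names to keep, default all 20.
#' @return numeric matrix, one row per sample.
#' @export
signal_matrix <- function(recording, channels = channel_groups()$channel) {
  missing_ch <- setdiff(channels, names(recording))
  if (length(missing_ch) > 0)
    abort(paste0("Recording is missing channel(s): ",
                 paste(missing_ch, collapse = ", ")))
  as.matrix(recording[, channels, drop = FALSE])
}

#' Sampling rate of a recording
#' @param recording a `gait_recording`.
#' @return sampling rate in Hz (defaults to 40 if the attribute is absent).
#' @export
sampling_rate <- function(recording) {
  fs <- attr(recording, "sampling_rate_hz")
  if (is.null(fs)) 40 else fs
}
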