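#' Sample-level confusion counts
#'
#' @param predicted 0/1 predictions.
#' @param target 0/1 labels.
#' @return one-row tibble with `tp`, `tn`, `fp`, `fn`
#'   (`tp+tn+fp+fn == length(target)`).
#' @export
confusion_counts <- function(predicted, target) {
  if (length(predicted) != length(target))
    abort("`predicted` and `target` must have the same length.")
  predicted <- as.integer(predicted)
  target <- as.integer(target)
  stopifnot(all(predicted %in% 0:1), all(target %in% 0:1))
  tibble::tibble(
    tp = sum(predicted == 1L & target == 1L),
    tn = sum(predicted == 0L & target == 0L),
    fp = sum(predicted == 1L & target == 0L),
    fn = sum(predicted == 0L & target == 1L)
  )
}

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, sensitivity (recall), specificity and F1. A metric
#' whose denominator is zero (possible on the heavily imbalanced recordings
#' this system faces, e.g. a test split with no FoG at all) is reported as 0
#' and named in the `degenerate` column, with a warning, so every run yields
#' a complete row.
#'
#' @param counts a [confusion_counts()] row (or list with tp/tn/fp/fn).
#' @param quiet suppress the degenerate-metric warning.
#' @return one-row tibble: `accuracy`, `precision`, `sensitivity`,
#'   `specificity`, `f1`, `degenerate`.
#' @export
fog_metrics <- function(counts, quiet = FALSE) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  if (total == 0) abort("No evaluated samples.")
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- safe_div(tp, tp + fp)
  sensitivity <- safe_div(tp, tp + fn)
  specificity <- safe_div(tn, tn + fp)
  f1 <- if (!is.na(precision) && !is.na(sensitivity) &&
            (precision + sensitivity) > 0)
    2 * precision * sensitivity / (precision + sensitivity)
  else NA_real_
  vals <- c(precision = precision, sensitivity = sensitivity,
            specificity = specificity, f1 = f1)
  degenerate <- names(vals)[is.na(vals)]
  if (length(degenerate) > 0 && !quiet)
    warn(paste0("Zero-denominator metric(s) reported as 0: ",
                paste(degenerate, collapse = ", ")))
  vals[is.na(vals)] <- 0
  tibble::tibble(
    accuracy = (tp + tn) / total,
    precision = vals[["precision"]], sensitivity = vals[["sensitivity"]],
    specificity = vals[["specificity"]], f1 = vals[["f1"]],
    degenerate = paste(degenerate, collapse = ",")
  )
}

#' Maximal runs of 1s as half-open episodes
#'
#' @param labels 0/1 vector.
#' @return tibble with 0-based `start` (inclusive) and `end` (exclusive),
#'   ordered and disjoint.
#' @export
episodes_from_labels <- function(labels) {
  labels <- as.integer(labels)
  stopifnot(all(labels %in% 0:1))
  edges <- diff(c(0L, labels, 0L))
  tibble::tibble(start = which(edges == 1L) - 1L,
                 end = which(edges == -1L) - 1L)
}

#' Event-level detection report
#'
#' An episode counts as detected when at least one thresholded detection
#' falls inside it; its delay is the gap, in samples, between the episode
#' onset and the first detection within it. A false-positive event is a
#' maximal run of detections overlapping no labeled episode. Millisecond
#' delays use the sample period (25 ms at 40 Hz).
#'
#' @param trace a `detection_trace` from [run_stream()], or a 0/1 detection
#'   vector.
#' @param labels per-sample 0/1 FoG labels aligned with the trace.
#' @param fs sampling rate in Hz.
#' @return A `fog_event_report`: list with `n_episodes`, `n_detected`,
#'   `fp_events`, `episodes` (per-episode tibble), `mean_delay_samples` and
#'   `mean_delay_ms`.
#' @export
event_report <- function(trace, labels, fs = 40) {
  detected <- if (is.data.frame(trace)) trace$detected else as.integer(trace)
  if (length(detected) != length(labels))
    abort("`trace` and `labels` must be aligned.")
  eps <- episodes_from_labels(labels)
  det_idx <- which(detected == 1L) - 1L # 0-based

  per_ep <- purrr::pmap_dfr(eps, function(start, end) {
    inside <- det_idx[det_idx >= start & det_idx < end]
    tibble::tibble(start = start, end = end,
                   detected = length(inside) > 0,
                   delay_samples = if (length(inside) > 0)
                     min(inside) - start else NA_real_)
  })

  runs <- episodes_from_labels(detected)
  fp_events <- 0L
  if (nrow(runs) > 0) {
    overlaps <- purrr::map_lgl(seq_len(nrow(runs)), function(i) {
      any(runs$start[i] < eps$end & runs$end[i] > eps$start)
    })
    fp_events <- sum(!overlaps)
  }

  delays <- per_ep$delay_samples[per_ep$detected]
  mean_delay <- if (length(delays) > 0) mean(delays) else NA_real_
  structure(
    list(n_episodes = nrow(eps), n_detected = sum(per_ep$detected),
         fp_events = as.integer(fp_events), episodes = per_ep,
         mean_delay_samples = mean_delay,
         mean_delay_ms = samples_to_ms(mean_delay, fs), fs = fs),
    class = "fog_event_report"
  )
}

#' Convert a delay in samples to milliseconds
#'
#' @param samples delay in samples.
#' @param fs sampling rate in Hz (25 ms per sample at 40 Hz).
#' @return delay in milliseconds.
#' @export
samples_to_ms <- function(samples, fs = 40) samples * 1000 / fs

#' @export
print.fog_event_report <- function(x, ...) {
  cat(sprintf("<fog_event_report> %d/%d episodes detected, %d FP event(s)\n",
              x$n_detected, x$n_episodes, x$fp_events))
  if (!is.na(x$mean_delay_samples))
    cat(sprintf("  mean detection delay: %.2f samples (%.0f ms at %g Hz)\n",
                x$mean_delay_samples, x$mean_delay_ms, x$fs))
  invisible(x)
}

#' Sensor-group ablation
#'
#' Retrains the detector on a restricted channel set (the window length
#' shrinks to `group size * (ps + 1)`) and evaluates sample-level metrics on
#' the held-out split.
#'
#' @param recording a `gait_recording`.
#' @param sensor_groups non-empty subset of `c("CF", "ACC", "GYRO", "MA")`.
#' @param ps past samples per window.
#' @param train_config a [fog_train_config()].
#' @param threshold score threshold for the sample-level confusion counts.
#' @return one-row tibble: the sensor combination, its channel count, and the
#'   test-split metrics.
#' @export
ablation_harness <- function(recording, sensor_groups, ps = 39,
                             train_config = fog_train_config(),
                             threshold = 0.5) {
  groups <- unique(toupper(sensor_groups))
  if (length(groups) == 0) abort("`sensor_groups` must be non-empty.")
  bad <- setdiff(groups, c("CF", "ACC", "GYRO", "MA"))
  if (length(bad) > 0)
    abort(paste0("Unknown sensor group(s): ", paste(bad, collapse = ", ")))
  ch <- channel_groups()
  use_ch <- ch$channel[ch$group %in% groups]
  fit <- fit_fog_detector(recording, ps, train_config, channels = use_ch)
  s <- predict(fit$model, fit$test$windows)
  m <- fog_metrics(confusion_counts(threshold_fn(s, threshold),
                                    fit$test$labels), quiet = TRUE)
  dplyr::bind_cols(
    tibble::tibble(combination = paste(sort(groups), collapse = "+"),
                   n_channels = length(use_ch)),
    m
  )
}
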