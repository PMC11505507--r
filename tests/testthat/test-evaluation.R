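test_that("confusion counts are standard cellwise tallies", {
  expect_equal(confusion_counts(c(1, 0, 1, 0), c(1, 1, 0, 0)),
               tibble::tibble(tp = 1L, tn = 1L, fp = 1L, fn = 1L))
  y <- withr::with_seed(3, rbinom(50, 1, 0.3))
  perfect <- confusion_counts(y, y)
  expect_equal(perfect$tp, sum(y))
  expect_equal(perfect$tn, sum(1 - y))
  expect_equal(perfect$fp + perfect$fn, 0L)
  inverted <- confusion_counts(1 - y, y)
  expect_equal(inverted$tp + inverted$tn, 0L)
  expect_equal(sum(unlist(inverted)), 50L)
  expect_error(confusion_counts(c(0, 1), c(0, 1, 0)), "length")
})

test_that("metrics follow their definitions and ranges", {
  m <- fog_metrics(tibble::tibble(tp = 1L, tn = 1L, fp = 1L, fn = 1L))
  expect_equal(unlist(m[c("accuracy", "precision", "sensitivity",
                          "specificity", "f1")], use.names = FALSE),
               rep(0.5, 5))
  y <- rep(c(0, 1), 10)
  mp <- fog_metrics(confusion_counts(y, y))
  expect_equal(unlist(mp[c("accuracy", "precision", "sensitivity",
                           "specificity", "f1")], use.names = FALSE),
               rep(1, 5))
})

test_that("zero-denominator metrics report 0 with a degenerate flag", {
  counts <- confusion_counts(rep(0, 10), rep(0, 10)) # no positives anywhere
  expect_warning(m <- fog_metrics(counts), "Zero-denominator")
  expect_equal(m$precision, 0)
  expect_equal(m$sensitivity, 0)
  expect_match(m$degenerate, "precision")
  expect_error(fog_metrics(tibble::tibble(tp = 0L, tn = 0L, fp = 0L,
                                          fn = 0L)))
})

test_that("episodes are maximal half-open runs of ones", {
  eps <- episodes_from_labels(c(0, 1, 1, 0, 1))
  expect_equal(eps$start, c(1L, 4L))
  expect_equal(eps$end, c(3L, 5L))
  expect_equal(nrow(episodes_from_labels(rep(0, 8))), 0L)
  all_on <- episodes_from_labels(rep(1, 6))
  expect_equal(all_on$start, 0L)
  expect_equal(all_on$end, 6L)
})

test_that("event report counts detections, delays and FP events", {
  er <- event_report(c(0, 0, 0, 1, 0, 0), c(0, 0, 1, 1, 1, 0))
  expect_equal(er$n_episodes, 1L)
  expect_equal(er$n_detected, 1L)
  expect_equal(er$mean_delay_samples, 1)
  expect_equal(er$fp_events, 0L)

  # detection exactly at onsets: zero delay; detached runs count as FP events
  labels <- c(0, 1, 1, 0, 0, 0, 1, 1, 1, 0)
  detected <- c(0, 1, 0, 0, 1, 0, 1, 0, 0, 1)
  er2 <- event_report(detected, labels)
  expect_equal(er2$n_detected, 2L)
  expect_equal(er2$mean_delay_samples, 0)
  expect_equal(er2$fp_events, 2L) # runs at t=4 and t=9
  expect_true(all(tidy(er2)$delay_samples >= 0, na.rm = TRUE))
})

test_that("delay converts to milliseconds at 25 ms per sample", {
  expect_equal(samples_to_ms(10.45, 40), 261.25)
  expect_equal(round(samples_to_ms(10.45, 40)), 261)
  expect_equal(samples_to_ms(1, 40), 25)
  er <- event_report(c(0, 1, 0, 0), c(1, 1, 0, 0), fs = 40)
  expect_equal(er$mean_delay_ms, er$mean_delay_samples * 25)
})

test_that("sensor-group ablation trains on the restricted channel set", {
  rec <- generate_recording(tiny_sim(seed = 91L))
  cfg <- fog_train_config(epochs = 3, batch_size = 64, seed = 7)

  one <- ablation_harness(rec, "MA", ps = 9, train_config = cfg)
  expect_equal(one$n_channels, 4L)
  expect_equal(one$combination, "MA")

  all4 <- ablation_harness(rec, c("CF", "ACC", "GYRO", "MA"), ps = 9,
                           train_config = cfg)
  expect_equal(all4$n_channels, 20L)
  expect_gt(all4$accuracy, 0.5)

  again <- ablation_harness(rec, c("CF", "ACC", "GYRO", "MA"), ps = 9,
                            train_config = cfg)
  expect_identical(all4, again) # deterministic given seed and subset

  expect_error(ablation_harness(rec, character(0)), "non-empty")
  expect_error(ablation_harness(rec, "EMG"), "Unknown")
})
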