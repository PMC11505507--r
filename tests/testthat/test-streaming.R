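test_that("the threshold function is strict", {
  expect_equal(threshold_fn(0.95, 0.9), 1L)
  expect_equal(threshold_fn(0.9, 0.9), 0L)
  expect_equal(threshold_fn(0.25, 0.2), 1L)
})

test_that("lowering the threshold never loses detections", {
  scores <- withr::with_seed(1, runif(500))
  thresholds <- sort(runif(10, 0.05, 0.95), decreasing = TRUE)
  prev <- integer(0)
  for (thr in thresholds) {
    cur <- which(threshold_fn(scores, thr) == 1L)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("an isolated detection keeps the cue active for exactly 120 samples", {
  T_n <- 400
  hit <- 100L # 0-based detection index
  stub <- function(window, t) if (t == hit) 1.0 else 0.0
  rec_mat <- random_recording_matrix(T_n)
  rec <- tibble::as_tibble(as.data.frame(rec_mat))
  trace <- run_stream(rec, stub, detector_config(threshold = 0.9))

  expect_equal(trace$detected[hit + 1L], 1L)
  active <- which(trace$cue_active == 1L) - 1L
  expect_identical(active, hit:(hit + 119L))
  expect_equal(trace$cue_active[hit + 121L], 0L) # off at t = hit + 120
  expect_equal(trace$fog_condition[hit + 1L], 3L)
})

test_that("a second detection restarts the countdown", {
  stub <- function(window, t) if (t %in% c(100L, 150L)) 1.0 else 0.0
  rec <- tibble::as_tibble(as.data.frame(random_recording_matrix(400)))
  trace <- run_stream(rec, stub, detector_config())
  active <- which(trace$cue_active == 1L) - 1L
  expect_identical(active, 100:(150 + 119))
})

test_that("without detections the state machine stays silent", {
  stub <- function(window, t) 0.0
  rec <- tibble::as_tibble(as.data.frame(random_recording_matrix(300)))
  trace <- run_stream(rec, stub, detector_config())
  expect_true(all(trace$fog_condition == 0L))
  expect_true(all(trace$cue_active == 0L))
  expect_equal(nrow(cue_events(trace)), 0L)
})

test_that("a label-perfect stub cues every episode and trace invariants hold", {
  rec <- generate_recording(tiny_sim(seed = 55L))
  labels <- rec$label
  stub <- function(window, t) as.numeric(labels[t + 1L])
  trace <- run_stream(rec, stub, detector_config())

  expect_identical(trace$cue_active, as.integer(trace$fog_condition > 0L))
  expect_true(all(trace$fog_condition %in% 0:3))
  expect_true(all(trace$fog_condition[trace$detected == 1L] == 3L))

  er <- event_report(trace, labels)
  expect_equal(er$n_detected, er$n_episodes)
  expect_equal(er$fp_events, 0L)
  expect_equal(er$mean_delay_samples, 0)

  events <- cue_events(trace)
  expect_true(all(events$event %in% c("cue_on", "cue_off")))
  expect_equal(sum(events$event == "cue_on"),
               nrow(episodes_from_labels(trace$cue_active)))
})

test_that("streamed scores equal batch predictions bitwise", {
  for (ps in c(0L, 15L)) {
    rec <- generate_recording(tiny_sim(seed = 60L + ps, duration_s = 30))
    model <- build_fog_model(fog_model_config(ps = ps), seed = ps + 1L)
    trace <- run_stream(rec, model, detector_config())
    offline <- predict(model, batch_windows(rec, ps)$windows)
    expect_identical(trace$score[(ps + 1L):nrow(rec)], offline)
    expect_true(all(trace$score[seq_len(ps)] == 0)) # warm-up emits 0
  }
})

test_that("detector configuration is validated", {
  expect_error(detector_config(threshold = 0), "strictly")
  expect_error(detector_config(threshold = 1), "strictly")
  expect_error(detector_config(cue_duration_s = 2, fog_condition_max = 3L),
               "one unit per second")
})

test_that("run_stream rejects a channel mismatch", {
  rec <- generate_recording(tiny_sim(seed = 70L, duration_s = 10))
  rec$acc1_x <- NULL
  model <- build_fog_model(fog_model_config(ps = 3), seed = 1)
  expect_error(run_stream(rec, model), "channel")
})
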