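test_that("architecture arithmetic matches the deployed shapes", {
  cfg <- fog_model_config(ps = 39)
  expect_equal(cfg$input_len, 800L)
  expect_equal(cfg$flatten_len, 1280L)
  expect_equal(fog_model_config(ps = 15)$flatten_len, 32 * 16)
  expect_error(fog_model_config(ps = -1))
  expect_error(fog_model_config(conv_kernel = 4)) # same padding needs odd kernel
})

test_that("untrained models map any window to a finite score in [0, 1]", {
  m <- build_fog_model(fog_model_config(ps = 5), seed = 2)
  w <- withr::with_seed(1, rnorm(120))
  s <- predict(m, w)
  expect_true(is.finite(s) && s >= 0 && s <= 1)
  expect_identical(predict(m, w), s) # bitwise repeatable
})

test_that("a zeroed output layer scores sigmoid(0) = 0.5", {
  m <- build_fog_model(fog_model_config(ps = 3), seed = 1)
  m$params$wout[] <- 0
  m$params$bout[] <- 0
  expect_equal(predict(m, rep(0, 80)), 0.5)
})

test_that("predict validates window length", {
  m <- build_fog_model(fog_model_config(ps = 3), seed = 1)
  expect_error(predict(m, rep(0, 79)), "length")
})

test_that("training reduces the loss and is seed-deterministic", {
  fit <- tiny_fit()
  hist <- tidy(fit$model)
  expect_equal(nrow(hist), 3L)
  expect_true(all(diff(hist$loss[1:3]) < 0))

  # duplicated training under the same seed reproduces the weights exactly
  rec <- generate_recording(tiny_sim())
  tr <- batch_windows(split_recording(rec, 0.6)$train, 9)
  cfg <- fog_train_config(epochs = 3, batch_size = 64, seed = 5)
  m1 <- fog_train(build_fog_model(fog_model_config(ps = 9), seed = 5),
                  tr$windows, tr$labels, cfg)
  expect_identical(m1$params, fit$model$params)
})

test_that("a single-class training split is rejected with advice", {
  rec <- generate_recording(sim_config(duration_s = 20, n_fog_episodes = 0,
                                       seed = 4))
  bw <- batch_windows(rec, 5)
  m <- build_fog_model(fog_model_config(ps = 5), seed = 1)
  expect_error(fog_train(m, bw$windows, bw$labels),
               class = "fogcue_single_class_error")
})

test_that("the trained detector separates FoG from gait on held-out data", {
  fit <- tiny_fit()
  s <- predict(fit$model, fit$test$windows)
  m <- fog_metrics(confusion_counts(threshold_fn(s, 0.5), fit$test$labels),
                   quiet = TRUE)
  expect_gt(m$f1, 0.8)
})

test_that("tune_past_samples scores the grid and returns one winner", {
  rec <- generate_recording(tiny_sim(seed = 77L, duration_s = 40))
  cfg <- fog_train_config(epochs = 2, batch_size = 64, seed = 3)
  out <- tune_past_samples(rec, ps_grid = c(3, 7), train_config = cfg)
  expect_equal(nrow(out$scores), 2L)
  expect_true(out$best_ps %in% c(3L, 7L))

  single <- tune_past_samples(rec, ps_grid = 5, train_config = cfg)
  expect_equal(single$best_ps, 5L)
  expect_error(tune_past_samples(rec, integer(0)), "non-empty")
})

test_that("model files round-trip bitwise and reject corruption", {
  fit <- tiny_fit()
  path <- withr::local_tempfile(fileext = ".fogmodel")
  save_fog_model(fit$model, path)
  reloaded <- load_fog_model(path)
  expect_identical(reloaded$params, fit$model$params)

  w <- fit$test$windows[1:50, ]
  expect_identical(predict(reloaded, w), predict(fit$model, w))

  expect_error(load_fog_model(path, expected_ps = 39), "ps")

  bad <- withr::local_tempfile(fileext = ".fogmodel")
  writeLines("not a model", bad)
  expect_error(load_fog_model(bad))
})
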