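test_that("activity schedule tiles the recording and honours episode count and prevalence", {
  cfg <- sim_config(duration_s = 350, n_fog_episodes = 13,
                    fog_prevalence = 0.154, seed = 3)
  sch <- make_activity_schedule(cfg)
  T_n <- 350 * 40
  expect_equal(sch$start[1], 0L)
  expect_equal(max(sch$end), T_n)
  expect_equal(sch$start[-1], sch$end[-nrow(sch)]) # contiguous tiling

  fog <- sch[sch$kind == "fog", ]
  expect_equal(nrow(fog), 13L)
  share <- sum(fog$end - fog$start) / T_n
  expect_lt(abs(share - 0.154), 0.031)

  # fog episodes separated by at least 1 s of non-fog activity
  gaps <- fog$start[-1] - fog$end[-nrow(fog)]
  expect_true(all(gaps >= 40))
})

test_that("schedules with no FoG episodes produce all-zero labels", {
  cfg <- sim_config(duration_s = 20, n_fog_episodes = 0, seed = 2)
  sch <- make_activity_schedule(cfg)
  expect_false(any(sch$kind == "fog"))
  rec <- generate_recording(cfg)
  expect_true(all(rec$label == 0L))
})

test_that("infeasible FoG demand raises a configuration error", {
  cfg <- sim_config(duration_s = 10, n_fog_episodes = 5,
                    fog_duration_s_range = c(3, 5), fog_prevalence = 0.5)
  expect_error(make_activity_schedule(cfg), class = "fogcue_config_error")
})

test_that("generation is deterministic given the seed and differs across seeds", {
  cfg <- tiny_sim(seed = 9L)
  r1 <- generate_recording(cfg)
  r2 <- generate_recording(cfg)
  expect_identical(r1, r2)
  r3 <- generate_recording(tiny_sim(seed = 10L))
  expect_false(isTRUE(all.equal(signal_matrix(r1), signal_matrix(r3))))
  expect_identical(names(r1), names(r3)) # same schema
})

test_that("recording length follows duration x sampling rate", {
  expect_equal(nrow(generate_recording(
    sim_config(duration_s = 237, n_fog_episodes = 2, seed = 1))), 9480L)
  expect_equal(nrow(generate_recording(
    sim_config(duration_s = 1, n_fog_episodes = 0, seed = 1))), 40L)
})

test_that("standing segments are zero-mean noise on every channel", {
  cfg <- sim_config(duration_s = 120, n_fog_episodes = 0,
                    activity_mix = c(walk = 0, stand = 1, turn = 0), seed = 21)
  rec <- generate_recording(cfg)
  expect_true(all(rec$activity == "stand"))
  S <- signal_matrix(rec)
  ch <- channel_groups()
  sd_of <- c(ACC = cfg$noise_sd[["acc"]], GYRO = cfg$noise_sd[["gyro"]],
             CF = cfg$noise_sd[["cf"]], MA = cfg$noise_sd[["ma"]])[ch$group]
  bound <- 3 * sd_of / sqrt(nrow(S))
  expect_true(all(abs(colMeans(S)) < bound))
})

test_that("walking shows a dominant 1 Hz spectral peak on accelerometer channels", {
  cfg <- sim_config(duration_s = 120, n_fog_episodes = 0,
                    activity_mix = c(walk = 1, stand = 0, turn = 0),
                    noise_sd = c(acc = 1e-6, gyro = 1e-6, cf = 1e-6, ma = 1e-6),
                    seed = 5)
  rec <- generate_recording(cfg)
  acc_ch <- channel_groups()$channel[channel_groups()$group == "ACC"]
  for (c_i in acc_ch) {
    sp <- stats::spec.pgram(stats::ts(rec[[c_i]], frequency = 40),
                            plot = FALSE, taper = 0)
    peak <- sp$freq[which.max(sp$spec)]
    expect_lt(abs(peak - 1), 0.2)
  }
})

test_that("FoG segments carry more 3-8 Hz band power than walking", {
  cfg <- sim_config(duration_s = 200, n_fog_episodes = 5,
                    fog_prevalence = 0.15, seed = 8)
  rec <- generate_recording(cfg)
  acc_ch <- channel_groups()$channel[channel_groups()$group == "ACC"]
  band_power <- function(x) {
    sp <- stats::spec.pgram(stats::ts(x, frequency = 40), plot = FALSE,
                            taper = 0)
    sum(sp$spec[sp$freq >= 3 & sp$freq <= 8])
  }
  fog_idx <- which(rec$activity == "fog")
  walk_idx <- which(rec$activity == "walk")
  n <- min(length(fog_idx), length(walk_idx), 1600)
  for (c_i in acc_ch) {
    expect_gt(band_power(rec[[c_i]][fog_idx[seq_len(n)]]),
              band_power(rec[[c_i]][walk_idx[seq_len(n)]]))
  }
})

test_that("label share tracks each cohort prevalence within 20% relative", {
  for (prev in c(0.015, 0.047, 0.086, 0.154)) {
    shares <- vapply(1:10, function(seed) {
      cfg <- sim_config(duration_s = 300, n_fog_episodes = 6,
                        fog_prevalence = prev, fog_duration_s_range = c(1, 6),
                        seed = seed)
      sch <- make_activity_schedule(cfg)
      fog <- sch[sch$kind == "fog", ]
      sum(fog$end - fog$start) / max(sch$end)
    }, numeric(1))
    expect_true(all(abs(shares - prev) / prev <= 0.2))
  }
})

test_that("labels are 1 exactly on fog activity and signals are finite float32", {
  rec <- generate_recording(tiny_sim(seed = 14L))
  expect_identical(rec$label, as.integer(rec$activity == "fog"))
  S <- signal_matrix(rec)
  expect_true(all(is.finite(S)))
  expect_identical(S, as_float32(S)) # single-precision contract
})
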