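test_that("rolling buffer emits 800-feature windows after warm-up at ps = 39", {
  buf <- rolling_buffer(39, 20)
  S <- random_recording_matrix(40)
  for (t in 1:39) {
    out <- push_sample(buf, S[t, ])
    buf <- out$buffer
    expect_null(out$window)
  }
  out <- push_sample(buf, S[40, ])
  expect_length(out$window, 800L)
})

test_that("ps = 0 buffers emit each sample unchanged", {
  buf <- rolling_buffer(0, 20)
  s <- as.numeric(random_recording_matrix(1))
  out <- push_sample(buf, s)
  expect_identical(out$window, s)
})

test_that("window ordering is current sample first, then increasing lag", {
  buf <- rolling_buffer(2, 3)
  s0 <- c(1, 2, 3); s1 <- c(4, 5, 6); s2 <- c(7, 8, 9); s3 <- c(10, 11, 12)
  for (s in list(s0, s1)) buf <- push_sample(buf, s)$buffer
  out <- push_sample(buf, s2)
  expect_identical(out$window, c(s2, s1, s0))
  out <- push_sample(out$buffer, s3)
  expect_identical(out$window, c(s3, s2, s1))
})

test_that("push_sample rejects malformed samples", {
  buf <- rolling_buffer(3, 20)
  expect_error(push_sample(buf, rep(0, 19)), "20")
  expect_error(push_sample(buf, c(rep(0, 19), NA)), "20")
})

test_that("batch windowing yields T - ps aligned windows", {
  S <- random_recording_matrix(100)
  bw <- batch_windows(S, 39)
  expect_equal(dim(bw$windows), c(61L, 800L))
  expect_identical(bw$t, 39:99)

  bw0 <- batch_windows(S, 0)
  expect_equal(nrow(bw0$windows), 100L)
  expect_identical(bw0$windows[7, ], unname(S[7, ]))

  expect_error(batch_windows(S, 100), "exceed")
})

test_that("batch and streamed windows are bit-identical", {
  for (ps in c(0L, 3L, 15L)) {
    S <- random_recording_matrix(80, seed = ps + 2)
    bw <- batch_windows(S, ps)
    buf <- rolling_buffer(ps, 20)
    k <- 0L
    for (t in seq_len(nrow(S))) {
      out <- push_sample(buf, S[t, ])
      buf <- out$buffer
      if (!is.null(out$window)) {
        k <- k + 1L
        expect_identical(out$window, unname(bw$windows[k, ]))
      }
    }
    expect_equal(k, nrow(bw$windows))
  }
})

test_that("window length follows 20 * (ps + 1) across the tuning grid", {
  S <- random_recording_matrix(120)
  for (ps in c(0, 15, 30, 39, 40, 60, 100))
    expect_equal(ncol(batch_windows(S, ps)$windows), 20 * (ps + 1))
})

test_that("batch windows aligned to recording labels", {
  rec <- generate_recording(tiny_sim(seed = 31L))
  bw <- batch_windows(rec, 10)
  expect_identical(bw$labels, rec$label[11:nrow(rec)])
})

test_that("static normalization matches (x - mu) / sigma", {
  expect_equal(normalize_static(5, 3, 2), 1.0)
  expect_equal(normalize_static(3, 3, 2), 0.0)
  expect_equal(normalize_static(3 + 2, 3, 2), 1.0)
  expect_error(normalize_static(1, 0, 0), "positive")
  m <- matrix(1:6, 3, 2)
  out <- normalize_static(m, c(0, 0), c(1, 2))
  expect_equal(out[, 2], (4:6) / 2)
})

test_that("complementary filter follows its recursion", {
  acc <- c(0.3, 0.5, 0.1)
  expect_equal(complementary_filter(acc, c(0, 0, 0), alpha = 0), acc)
  expect_equal(complementary_filter(c(2, 0, 0, 0), rep(0, 4), alpha = 1),
               rep(2, 4))
  theta <- complementary_filter(rep(0, 3), rep(1, 3), alpha = 0.98,
                                dt = 0.025)
  expect_equal(theta[3], 0.04851, tolerance = 1e-12)
  expect_error(complementary_filter(1:3, 1:4), "length")
})
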