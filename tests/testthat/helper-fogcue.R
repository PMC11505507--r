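# Small shared fixtures. Training fixtures are deliberately tiny so the unit
# suite stays fast; full-scale runs live in the acceptance tests.

tiny_sim <- function(seed = 101L, duration_s = 60, n_fog = 4,
                     prevalence = 0.12) {
  sim_config(duration_s = duration_s, n_fog_episodes = n_fog,
             fog_prevalence = prevalence, fog_duration_s_range = c(1, 2),
             seed = seed)
}

# one small trained detector, computed once and reused across tests
tiny_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      rec <- generate_recording(tiny_sim())
      cache <<- fit_fog_detector(
        rec, ps = 9,
        fog_train_config(epochs = 3, batch_size = 64, seed = 5))
    }
    cache
  }
})

random_recording_matrix <- function(T_n, n_ch = 20, seed = 1) {
  withr::with_seed(seed, {
    as_float32(matrix(rnorm(T_n * n_ch), T_n, n_ch,
                      dimnames = list(NULL, channel_groups()$channel)))
  })
}
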