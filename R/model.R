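#' Architecture configuration for the CNN+RNN FoG classifier
#'
#' The compact network deployed on the wearable: a length `n_channels*(ps+1)`
#' window is normalized feature-wise (learned scale/offset, frozen moments),
#' reshaped to `n_channels x (ps+1)` (channels x time), convolved along time
#' (`conv_filters` kernels, same-length padding, ReLU), viewed as a sequence
#' of `ps+1` steps of `conv_filters` features (a flattened feature count of
#' `conv_filters*(ps+1)`; 1280 at the defaults with `ps = 39`), passed through
#' two simple tanh recurrent layers, and read out by a single sigmoid neuron.
#'
#' @param ps past samples per window (39 gives the 800-feature input).
#' @param n_channels input channels per sample.
#' @param conv_filters convolution filters.
#' @param conv_kernel convolution kernel width (odd; same-length padding).
#' @param recurrent_units sizes of the two recurrent layers.
#' @return A `fog_model_config` list with derived fields `input_len` and
#'   `flatten_len`.
#' @export
fog_model_config <- function(ps = 39, n_channels = 20, conv_filters = 32,
                             conv_kernel = 5, recurrent_units = c(64, 32)) {
  stopifnot(ps >= 0, n_channels >= 1, conv_filters >= 1,
            conv_kernel %% 2 == 1, length(recurrent_units) == 2)
  structure(
    list(ps = as.integer(ps), n_channels = as.integer(n_channels),
         conv_filters = as.integer(conv_filters),
         conv_kernel = as.integer(conv_kernel),
         recurrent_units = as.integer(recurrent_units),
         input_len = as.integer(n_channels * (ps + 1)),
         flatten_len = as.integer(conv_filters * (ps + 1)),
         output_units = 1L),
    class = "fog_model_config"
  )
}

#' Build an (untrained) FoG classifier
#'
#' All parameters are initialized Glorot-uniform and stored as exactly
#' float32-representable values; every forward pass runs in 32-bit floats,
#' matching the embedded target.
#'
#' @param config a [fog_model_config()].
#' @param seed integer seed for weight initialization.
#' @return A `fog_model` object with `threshold_default = 0.9`.
#' @export
build_fog_model <- function(config = fog_model_config(), seed = 1L) {
  params <- fog_init_params(config$n_channels, config$ps, config$conv_filters,
                            config$conv_kernel, config$recurrent_units[1],
                            config$recurrent_units[2], as.integer(seed))
  structure(
    list(config = config, params = params, trained = FALSE,
         history = NULL, threshold_default = 0.9),
    class = "fog_model"
  )
}

#' Training configuration
#'
#' @param split_fraction chronological train fraction (train on the first
#'   60% of a recording, test on the remaining 40%).
#' @param epochs training epochs.
#' @param batch_size mini-batch size.
#' @param learning_rate Adam learning rate.
#' @param class_weighting use inverse-frequency class weights; recommended
#'   because FoG is a small minority of samples.
#' @param seed seed controlling initialization and batch shuffling.
#' @return A `fog_train_config` list.
#' @export
fog_train_config <- function(split_fraction = 0.6, epochs = 6,
                             batch_size = 128, learning_rate = 1e-3,
                             class_weighting = TRUE, seed = 1L) {
  stopifnot(split_fraction > 0, split_fraction < 1, epochs >= 1,
            batch_size >= 1, learning_rate > 0)
  structure(
    list(split_fraction = split_fraction, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), learning_rate = learning_rate,
         class_weighting = isTRUE(class_weighting), seed = as.integer(seed)),
    class = "fog_train_config"
  )
}

#' Train the FoG classifier
#'
#' Weighted binary cross-entropy, Adam, backpropagation through time; the
#' normalization layer's per-feature moments are frozen from the training
#' windows at the start of training and gamma/beta are then learned by
#' gradient. Deterministic given the seed.
#'
#' @param model a [build_fog_model()] object.
#' @param windows window matrix from [batch_windows()].
#' @param labels aligned 0/1 labels.
#' @param train_config a [fog_train_config()].
#' @return The trained `fog_model`, with a `history` tibble of per-epoch
#'   mean training loss.
#' @export
fog_train <- function(model, windows, labels, train_config = fog_train_config()) {
  stopifnot(inherits(model, "fog_model"))
  cfg <- model$config
  if (ncol(windows) != cfg$input_len)
    abort(sprintf("Windows have %d features; model expects %d.",
                  ncol(windows), cfg$input_len))
  if (nrow(windows) != length(labels))
    abort("`windows` and `labels` are not aligned.")
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    abort(paste("Training split contains a single class;",
                "resimulate or extend the recording so both FoG and non-FoG",
                "samples are present."),
          class = "fogcue_single_class_error")

  # freeze normalization moments from the training windows
  mu <- colMeans(windows)
  v <- colMeans(windows^2) - mu^2
  v[v < 1e-8] <- 1e-8
  model$params$mu <- as_float32(mu)
  model$params$var <- as_float32(v)

  if (train_config$class_weighting) {
    n <- length(labels); n1 <- sum(labels == 1L); n0 <- n - n1
    w0 <- n / (2 * n0); w1 <- n / (2 * n1)
  } else {
    w0 <- 1; w1 <- 1
  }

  fit <- fog_train_cpp(model$params, windows, labels,
                       cfg$n_channels, cfg$ps, cfg$conv_filters,
                       cfg$conv_kernel, cfg$recurrent_units[1],
                       cfg$recurrent_units[2],
                       train_config$epochs, train_config$batch_size,
                       train_config$learning_rate, w0, w1,
                       train_config$seed)
  model$params <- fit$params
  model$trained <- TRUE
  model$history <- tibble::tibble(epoch = seq_along(fit$loss),
                                  loss = as.numeric(fit$loss))
  model
}

#' Predict FoG scores for windows
#'
#' Runs the single-precision forward pass. The scalar execution path is
#' sequential and per-window, so batch prediction and one-window-at-a-time
#' streaming produce bit-identical scores.
#'
#' @param object a `fog_model`.
#' @param windows window matrix (rows = windows) or a single window vector.
#' @param ... unused.
#' @return numeric vector of scores in [0, 1].
#' @export
predict.fog_model <- function(object, windows, ...) {
  if (!is.matrix(windows)) windows <- matrix(windows, nrow = 1)
  cfg <- object$config
  if (ncol(windows) != cfg$input_len)
    abort(sprintf("Window length %d does not match model input length %d.",
                  ncol(windows), cfg$input_len))
  fog_forward(object$params, windows, cfg$n_channels, cfg$ps,
              cfg$conv_filters, cfg$conv_kernel, cfg$recurrent_units[1],
              cfg$recurrent_units[2])
}

#' Chronological train/test split of a recording
#'
#' @param recording a `gait_recording`.
#' @param split_fraction fraction of samples (from the start) used for
#'   training.
#' @return list of two `gait_recording`s, `train` and `test`.
#' @export
split_recording <- function(recording, split_fraction = 0.6) {
  T_n <- nrow(recording)
  n_train <- floor(split_fraction * T_n)
  fs <- sampling_rate(recording)
  train <- recording[seq_len(n_train), ]
  test <- recording[(n_train + 1L):T_n, ]
  list(train = set_recording_attrs(train, fs, attr(recording, "sim_config")),
       test = set_recording_attrs(test, fs, attr(recording, "sim_config")))
}

#' Fit a FoG detector on a recording's training split
#'
#' Convenience wrapper: splits the recording chronologically, windows each
#' part, trains on the first split and returns the model together with the
#' held-out windows.
#'
#' @param recording a `gait_recording`.
#' @param ps past samples per window.
#' @param train_config a [fog_train_config()].
#' @param channels channel columns to use (default all 20).
#' @return list with `model`, `test` (list of `windows`, `labels`, `t` on the
#'   held-out split) and `split`.
#' @export
fit_fog_detector <- function(recording, ps = 39,
                             train_config = fog_train_config(),
                             channels = channel_groups()$channel) {
  parts <- split_recording(recording, train_config$split_fraction)
  tr <- batch_windows(parts$train, ps, channels)
  te <- batch_windows(parts$test, ps, channels)
  cfg <- fog_model_config(ps = ps, n_channels = length(channels))
  model <- build_fog_model(cfg, seed = train_config$seed)
  model <- fog_train(model, tr$windows, tr$labels, train_config)
  list(model = model, test = te, split = parts)
}

#' Tune the past-samples hyperparameter
#'
#' Trains one model per candidate `ps` on the chronological training split
#' and scores F1 (at a 0.5 score threshold) on the held-out split. Ties are
#' broken toward the smaller, cheaper `ps`.
#'
#' @param recording a `gait_recording`.
#' @param ps_grid integer candidates; the deployment grid is
#'   `c(15, 30, 40, 60, 100)`.
#' @param train_config a [fog_train_config()].
#' @return list with `best_ps` and `scores`, a tibble of `ps` and test F1.
#' @export
tune_past_samples <- function(recording, ps_grid = c(15, 30, 40, 60, 100),
                              train_config = fog_train_config()) {
  if (length(ps_grid) == 0) abort("`ps_grid` must be non-empty.")
  scores <- purrr::map_dbl(ps_grid, function(ps) {
    fit <- fit_fog_detector(recording, ps, train_config)
    s <- predict(fit$model, fit$test$windows)
    m <- fog_metrics(confusion_counts(threshold_fn(s, 0.5), fit$test$labels),
                     quiet = TRUE)
    m$f1
  })
  tab <- tibble::tibble(ps = as.integer(ps_grid), f1 = scores)
  ordered <- dplyr::arrange(tab, dplyr::desc(.data$f1), .data$ps)
  list(best_ps = ordered$ps[1], scores = tab)
}

#' @export
print.fog_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<fog_model> ps=%d, %d channels -> input %d; conv %d@%d -> flatten %d; RNN %d/%d; %s\n",
    cfg$ps, cfg$n_channels, cfg$input_len, cfg$conv_filters, cfg$conv_kernel,
    cfg$flatten_len, cfg$recurrent_units[1], cfg$recurrent_units[2],
    if (x$trained) "trained" else "untrained"))
  invisible(x)
}
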