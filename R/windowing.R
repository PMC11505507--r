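#' Past-samples window preprocessing
#'
#' The classifier consumes, for every sample `t`, a flat vector of the current
#' sample's 20 channels followed by the channels of the `ps` preceding
#' samples:
#' `v = [u_{1,t} ... u_{20,t}, u_{1,t-1} ... u_{20,t-1}, ..., u_{20,t-ps}]`,
#' length `20 * (ps + 1)`. With the deployed default `ps = 39` this is the
#' 800-feature input. Offline (batch) and online (rolling-buffer) forms are
#' required to be bit-identical; both here are pure memory rearrangements, so
#' identity holds by construction.
#'
#' @name windowing
NULL

#' Create a rolling window buffer
#'
#' Holds the most recent `ps + 1` samples. No window (hence no prediction) is
#' emitted until the buffer is full: at 40 Hz the warm-up is at most 2.5 s
#' even at the maximum `ps = 100`.
#'
#' @param ps number of past samples per window.
#' @param n_channels channels per sample (20 for the full sensor set).
#' @return A `rolling_buffer` list with fields `ps`, `n_channels`, `data`
#'   (rows oldest to newest) and `fill_count`.
#' @export
rolling_buffer <- function(ps, n_channels = 20L) {
  stopifnot(ps >= 0, n_channels >= 1)
  structure(
    list(ps = as.integer(ps), n_channels = as.integer(n_channels),
         data = matrix(NA_real_, ps + 1L, n_channels), fill_count = 0L),
    class = "rolling_buffer"
  )
}

#' Push one sample into a rolling buffer
#'
#' Shifts the buffer one position (oldest sample drops out) and appends the
#' new sample. A window vector in Eq.-1 ordering (current sample's channels
#' first) is emitted once the buffer holds `ps + 1` samples.
#'
#' @param buffer a [rolling_buffer()].
#' @param sample numeric vector with exactly `n_channels` finite values.
#' @return list with elements `buffer` (updated) and `window` (numeric vector
#'   of length `n_channels * (ps + 1)`, or `NULL` during warm-up).
#' @export
push_sample <- function(buffer, sample) {
  if (length(sample) != buffer$n_channels || !all(is.finite(sample)))
    abort(sprintf("`sample` must hold exactly %d finite values.",
                  buffer$n_channels))
  n_rows <- buffer$ps + 1L
  if (n_rows > 1L)
    buffer$data[seq_len(n_rows - 1L), ] <- buffer$data[2:n_rows, ]
  buffer$data[n_rows, ] <- sample
  buffer$fill_count <- min(buffer$fill_count + 1L, n_rows)
  window <- NULL
  if (buffer$fill_count == n_rows)
    window <- as.vector(t(buffer$data[n_rows:1L, , drop = FALSE]))
  list(buffer = buffer, window = window)
}

#' Batch past-samples windows for a whole recording
#'
#' Offline form of the preprocessing: produces `T - ps` windows, window `k`
#' aligned with sample index `k + ps` (0-based) and its label. Row `k` is
#' bit-identical to the online window emitted by [push_sample()] at that
#' index.
#'
#' @param recording a `gait_recording`, or a plain numeric matrix of signals.
#' @param ps number of past samples.
#' @param channels channel columns to use (default all 20).
#' @return list with `windows` (matrix, `T - ps` rows), `labels` (aligned
#'   label vector, `NULL` if the input has no labels) and `t` (0-based sample
#'   indices of each window).
#' @export
batch_windows <- function(recording, ps, channels = channel_groups()$channel) {
  if (is.matrix(recording)) {
    S <- recording
    labels <- NULL
  } else {
    S <- signal_matrix(recording, intersect(channels, names(recording)))
    labels <- recording$label
  }
  T_n <- nrow(S)
  ps <- as.integer(ps)
  if (T_n <= ps)
    abort(sprintf("Recording length %d must exceed ps = %d.", T_n, ps))
  n_ch <- ncol(S)
  W <- matrix(0, T_n - ps, n_ch * (ps + 1L))
  for (lag in 0:ps)
    W[, (lag * n_ch + 1L):(lag * n_ch + n_ch)] <-
      S[(ps + 1L - lag):(T_n - lag), , drop = FALSE]
  list(windows = W,
       labels = if (!is.null(labels)) labels[(ps + 1L):T_n] else NULL,
       t = ps:(T_n - 1L))
}

#' Static z-score normalization
#'
#' The legacy offline normalization `y = (x - mu) / sigma` with dataset-wide
#' moments. The deployed model instead normalizes inside the network (learned
#' beta/gamma); this form is kept for preprocessing experiments.
#'
#' @param x numeric vector or matrix (columns = channels).
#' @param mu per-channel mean(s).
#' @param sigma per-channel standard deviation(s), all > 0.
#' @return normalized values, rounded to single precision.
#' @export
normalize_static <- function(x, mu, sigma) {
  if (any(sigma <= 0)) abort("`sigma` must be strictly positive.")
  if (is.matrix(x)) {
    out <- sweep(sweep(x, 2, mu), 2, sigma, "/")
  } else {
    out <- (x - mu) / sigma
  }
  as_float32(out)
}

#' First-order complementary filter for angle estimation
#'
#' Fuses an accelerometer-derived angle with an integrated gyroscope rate:
#' `theta_t = alpha * (theta_{t-1} + gyro_t * dt) + (1 - alpha) * acc_t`,
#' initialized at `theta_0 = acc_0`. The high-pass weight `alpha` defaults to
#' 0.98, a conventional choice that trusts the gyro over ~1 s and the
#' accelerometer for the long-run level.
#'
#' @param acc_angle accelerometer-derived angle series (degrees or radians).
#' @param gyro_rate gyroscope angular rate series, same units per second.
#' @param alpha blend weight in [0, 1].
#' @param dt sample period in seconds (1/40 at the recorder's rate).
#' @return fused angle series, same length and units as `acc_angle`.
#' @export
complementary_filter <- function(acc_angle, gyro_rate, alpha = 0.98,
                                 dt = 1 / 40) {
  if (length(acc_angle) != length(gyro_rate))
    abort("`acc_angle` and `gyro_rate` must have the same length.")
  stopifnot(alpha >= 0, alpha <= 1, dt > 0)
  n <- length(acc_angle)
  theta <- numeric(n)
  if (n == 0) return(theta)
  theta[1] <- acc_angle[1]
  for (t in seq_len(n - 1L) + 1L)
    theta[t] <- alpha * (theta[t - 1L] + gyro_rate[t] * dt) +
      (1 - alpha) * acc_angle[t]
  theta
}
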