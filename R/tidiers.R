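#' @export
tidy.fog_model <- function(x, ...) {
  if (is.null(x$history))
    return(tibble::tibble(epoch = integer(0), loss = numeric(0)))
  x$history
}

#' @export
glance.fog_model <- function(x, ...) {
  n_params <- sum(purrr::map_int(x$params, length))
  tibble::tibble(
    ps = x$config$ps, n_channels = x$config$n_channels,
    input_len = x$config$input_len, flatten_len = x$config$flatten_len,
    n_parameters = n_params, trained = x$trained,
    final_loss = if (is.null(x$history)) NA_real_
                 else utils::tail(x$history$loss, 1)
  )
}

#' @export
tidy.fog_event_report <- function(x, ...) x$episodes

#' @export
glance.fog_event_report <- function(x, ...) {
  tibble::tibble(
    n_episodes = x$n_episodes, n_detected = x$n_detected,
    fp_events = x$fp_events,
    mean_delay_samples = x$mean_delay_samples,
    mean_delay_ms = x$mean_delay_ms
  )
}
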