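MODEL_MAGIC <- "fogcue-model"
MODEL_VERSION <- 1L

#' Save / load a trained FoG classifier
#'
#' Container layout: one JSON header line (magic, version, architecture
#' configuration, training flag, array names and dimensions) followed by the
#' raw little-endian 32-bit float arrays in header order. Because every
#' parameter is float32-representable, a save/load round trip is bitwise
#' lossless and predictions are bit-identical.
#'
#' @param model a `fog_model`.
#' @param path file path.
#' @return `save_fog_model()` returns `path` invisibly; `load_fog_model()`
#'   returns the restored `fog_model`.
#' @export
save_fog_model <- function(model, path) {
  stopifnot(inherits(model, "fog_model"))
  arrays <- model$params
  header <- list(
    magic = MODEL_MAGIC, version = MODEL_VERSION,
    config = unclass(model$config), trained = model$trained,
    threshold_default = model$threshold_default,
    arrays = purrr::map(names(arrays), function(nm) {
      a <- arrays[[nm]]
      list(name = nm, dim = if (is.matrix(a)) dim(a) else length(a))
    })
  )
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA)
  writeBin(charToRaw(paste0(hdr, "\n")), con)
  for (nm in names(arrays))
    writeBin(as.numeric(arrays[[nm]]), con, size = 4L, endian = "little")
  invisible(path)
}

#' @param expected_ps if given, loading fails unless the stored model was
#'   built with this `ps`.
#' @rdname save_fog_model
#' @export
load_fog_model <- function(path, expected_ps = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  # read header line byte-wise up to the first newline
  hdr_raw <- raw(0)
  repeat {
    b <- readBin(con, "raw", 1L)
    if (length(b) == 0)
      abort("Corrupt model file: no header line found.")
    if (b == charToRaw("\n")) break
    hdr_raw <- c(hdr_raw, b)
  }
  header <- tryCatch(jsonlite::fromJSON(rawToChar(hdr_raw),
                                        simplifyVector = FALSE),
                     error = function(e) abort("Corrupt model file: unreadable header."))
  if (!identical(header$magic, MODEL_MAGIC))
    abort("Not a fogcue model file.")
  if (!identical(as.integer(header$version), MODEL_VERSION))
    abort(sprintf("Unsupported model file version %s.", header$version))
  cfg <- header$config
  config <- fog_model_config(ps = cfg$ps, n_channels = cfg$n_channels,
                             conv_filters = cfg$conv_filters,
                             conv_kernel = cfg$conv_kernel,
                             recurrent_units = unlist(cfg$recurrent_units))
  if (!is.null(expected_ps) && config$ps != as.integer(expected_ps))
    abort(sprintf("Model file has ps = %d but ps = %d was expected.",
                  config$ps, as.integer(expected_ps)))
  params <- list()
  for (a in header$arrays) {
    d <- unlist(a$dim)
    n <- prod(d)
    vals <- readBin(con, "numeric", n, size = 4L, endian = "little")
    if (length(vals) != n)
      abort("Corrupt model file: truncated array data.")
    params[[a$name]] <- if (length(d) == 2) matrix(vals, d[1], d[2]) else vals
  }
  structure(
    list(config = config, params = params,
         trained = isTRUE(header$trained), history = NULL,
         threshold_default = header$threshold_default),
    class = "fog_model"
  )
}
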