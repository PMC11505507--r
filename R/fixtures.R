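#' Packaged reference tables
#'
#' Small plain-text tables shipped with the package so summary statistics can
#' be recomputed offline: `patient_datasets()` describes the nine-patient
#' recording cohort (FoG share, episode count, sample count per recording);
#' `offline_accuracy()` holds the per-patient offline detection accuracy and
#' the tuned past-samples value of the raw-data classifier.
#'
#' @return tibbles.
#' @name fixtures
NULL

#' @rdname fixtures
#' @export
patient_datasets <- function() {
  path <- system.file("extdata", "patient_datasets.csv", package = "fogcue")
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname fixtures
#' @export
offline_accuracy <- function() {
  path <- system.file("extdata", "offline_accuracy.csv", package = "fogcue")
  readr::read_csv(path, show_col_types = FALSE)
}
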