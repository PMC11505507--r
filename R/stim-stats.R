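#' FoG probability of a recording condition
#'
#' The fraction of samples labeled FoG: `n_fog / n_total`.
#'
#' @param n_fog FoG samples.
#' @param n_total total samples (> 0).
#' @return fraction in [0, 1]; vectorized.
#' @export
fog_probability <- function(n_fog, n_total) {
  if (any(n_total <= 0)) abort("`n_total` must be positive.")
  if (any(n_fog < 0 | n_fog > n_total))
    abort("`n_fog` must lie in [0, n_total].")
  n_fog / n_total
}

#' Two-proportion Z-test for the stimulation effect
#'
#' Compares the FoG sample rate without stimulation (`r1`) against the rate
#' with stimulation (`r2`) using the unpooled standard error
#' `SE = sqrt(r1(1-r1)/n1 + r2(1-r2)/n2)` and `z = (r2 - r1)/SE`, so a
#' reduction under stimulation gives a negative z. The p-value is two-sided
#' from the standard normal CDF, and the percent reduction is
#' `(r1 - r2)/r1 * 100`.
#'
#' @param fog_without,total_without FoG and total sample counts without
#'   stimulation.
#' @param fog_with,total_with counts with stimulation.
#' @return A `fog_two_proportion` object with fields `r1`, `r2`, `se`, `z`,
#'   `p`, `reduction_pct` and the input counts. See [tidy()] / [glance()].
#' @export
two_proportion_test <- function(fog_without, total_without,
                                fog_with, total_with) {
  r1 <- fog_probability(fog_without, total_without)
  r2 <- fog_probability(fog_with, total_with)
  if (r1 == 0) abort("FoG rate without stimulation is zero; reduction undefined.")
  se <- sqrt(r1 * (1 - r1) / total_without + r2 * (1 - r2) / total_with)
  z <- if (se == 0) 0 else (r2 - r1) / se
  p <- min(1, 2 * pnorm(-abs(z)))
  if (z == 0) p <- 1
  structure(
    list(r1 = r1, r2 = r2, se = se, z = z, p = p,
         reduction_pct = (r1 - r2) / r1 * 100,
         n1 = total_without, x1 = fog_without,
         n2 = total_with, x2 = fog_with),
    class = "fog_two_proportion"
  )
}

#' @export
print.fog_two_proportion <- function(x, ...) {
  cat(sprintf(
    "<two-proportion z-test> r1=%.4f (no stim), r2=%.4f (stim); reduction %d%%\n  z = %.2f, p = %.3g\n",
    x$r1, x$r2, round(x$reduction_pct), x$z, x$p))
  invisible(x)
}

#' Monte-Carlo cross-check of the normal-approximation p-value
#'
#' Simulates both conditions' FoG counts under the pooled null rate and
#' returns the empirical two-sided p-value for the observed difference of
#' proportions (with the usual +1 correction so the estimate is never zero).
#' For moderate counts it agrees with the analytic p in order of magnitude.
#'
#' @inheritParams two_proportion_test
#' @param n_sims number of simulations (at least 1000).
#' @param seed integer seed.
#' @return empirical p-value.
#' @export
exact_binomial_check <- function(fog_without, total_without,
                                 fog_with, total_with,
                                 n_sims = 10000, seed = 1L) {
  if (n_sims < 1000) abort("`n_sims` must be at least 1000.")
  r1 <- fog_probability(fog_without, total_without)
  r2 <- fog_probability(fog_with, total_with)
  d_obs <- abs(r2 - r1)
  pooled <- (fog_without + fog_with) / (total_without + total_with)
  withr::with_seed(seed, {
    s1 <- rbinom(n_sims, total_without, pooled) / total_without
    s2 <- rbinom(n_sims, total_with, pooled) / total_with
  })
  (1 + sum(abs(s2 - s1) >= d_obs)) / (n_sims + 1)
}

#' Stimulation-effect table across patients
#'
#' Runs [two_proportion_test()] per patient on a long counts table (columns
#' `patient`, `condition` in with/without, `total`, `fog`), the layout of the
#' packaged fixture (see [stimulation_counts()]).
#'
#' @param counts counts tibble/data frame.
#' @return tibble, one row per patient: rates, percent reduction, z and p.
#' @export
stimulation_effect <- function(counts) {
  need <- c("patient", "condition", "total", "fog")
  if (!all(need %in% names(counts)))
    abort("`counts` needs columns patient, condition, total, fog.")
  counts |>
    dplyr::group_by(.data$patient) |>
    dplyr::group_modify(function(df, key) {
      w <- df[df$condition == "without", ]
      s <- df[df$condition == "with", ]
      if (nrow(w) != 1 || nrow(s) != 1)
        abort("Each patient needs one 'with' and one 'without' row.")
      tidy(two_proportion_test(w$fog, w$total, s$fog, s$total))
    }) |>
    dplyr::ungroup()
}

#' Packaged stimulation counts fixture
#'
#' Per-patient FoG and total sample counts for the with- and
#' without-stimulation recording conditions of the three real-time sessions
#' the package emulates (the without-stimulation rows are the training
#' recordings).
#'
#' @return tibble with columns `patient`, `condition`, `total`, `fog`.
#' @export
stimulation_counts <- function() {
  path <- system.file("extdata", "stimulation_counts.csv", package = "fogcue")
  readr::read_csv(path, show_col_types = FALSE)
}

#' @export
tidy.fog_two_proportion <- function(x, ...) {
  tibble::tibble(
    estimate1 = x$r1, estimate2 = x$r2, std.error = x$se,
    statistic = x$z, p.value = x$p, reduction_pct = x$reduction_pct
  )
}

#' @export
glance.fog_two_proportion <- function(x, ...) {
  tibble::tibble(
    statistic = x$z, p.value = x$p, reduction_pct = x$reduction_pct,
    n_without = x$n1, n_with = x$n2
  )
}
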