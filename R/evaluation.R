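#' Bland-Altman agreement statistics
#'
#' Summarises paired differences `estimate - reference`: their mean, sample
#' standard deviation (n - 1 denominator) and the limits of agreement at
#' mean plus/minus 1.96 SD. Translation-equivariant: shifting both
#' sequences by a constant leaves the report unchanged.
#'
#' @param estimates,references Equal-length numeric vectors (mmHg), length
#'   at least 2.
#' @return One-row tibble: `n`, `mean_error_mmHg`, `sd_error_mmHg`,
#'   `loa_low_mmHg`, `loa_high_mmHg`.
#' @export
bland_altman <- function(estimates, references) {
  if (length(estimates) != length(references)) {
    abort_param("`estimates` and `references` must have equal length.")
  }
  if (length(estimates) < 2) abort_param("at least 2 paired points are required.")
  d <- as.numeric(estimates) - as.numeric(references)
  m <- mean(d)
  s <- sd(d)
  tibble(n = length(d), mean_error_mmHg = m, sd_error_mmHg = s,
         loa_low_mmHg = m - 1.96 * s, loa_high_mmHg = m + 1.96 * s)
}

#' Squared Pearson correlation
#'
#' @param x,y Equal-length numeric vectors (length >= 3) with nonzero
#'   variance.
#' @return R-squared in \[0, 1\] (sign-blind: `y = -x` gives 1).
#' @export
correlation_r2 <- function(x, y) {
  if (length(x) != length(y)) abort_param("`x` and `y` must have equal length.")
  if (length(x) < 3) abort_param("at least 3 paired points are required for R^2.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("undefined correlation: one of the sequences has zero variance.",
          class = "pttbp_undefined_correlation")
  }
  stats::cor(x, y)^2
}

agreement_row <- function(est, ref, model, pressure_type) {
  n <- length(est)
  if (n >= 2) {
    ba <- bland_altman(est, ref)
  } else {
    ba <- tibble(n = n, mean_error_mmHg = if (n == 1) est - ref else NA_real_,
                 sd_error_mmHg = NA_real_, loa_low_mmHg = NA_real_,
                 loa_high_mmHg = NA_real_)
  }
  r2_ok <- n >= 3 && sd(est) > 0 && sd(ref) > 0
  reg <- if (n >= 2 && sd(ref) > 0) coef(lm(est ~ ref)) else c(NA_real_, NA_real_)
  dplyr::bind_cols(tibble(model = model, pressure_type = pressure_type), ba,
                   tibble(r2 = if (r2_ok) correlation_r2(est, ref) else NA_real_,
                          r2_defined = r2_ok,
                          regression_slope = unname(reg[2]),
                          regression_intercept = unname(reg[1])))
}

#' Session-level agreement between estimates and reference blood pressure
#'
#' Pairs each estimation session's estimate summary (the mean of its
#' per-beat estimates, since the oscillometric cuff yields a single
#' reference per session) with the session's resolved reference pressure,
#' and reports Bland-Altman statistics, R-squared and the least-squares
#' regression line for every model x pressure-type combination present.
#'
#' @param estimates Per-beat estimate tibble from [estimate_cohort()]
#'   (columns `subject_id`, `model`, `sbp_mmHg`, `dbp_mmHg`), or a
#'   pre-paired tibble (see `paired`).
#' @param analysis The [analyze_cohort()] result supplying each estimation
#'   session's resolved reference pressures.
#' @param paired Alternatively, supply the paired session-level tibble
#'   directly (`subject_id`, `model`, `pressure_type`, `estimate`,
#'   `reference`).
#' @return A `bp_agreement` tibble (one row per model x pressure type) with
#'   the paired data in attribute `"paired"`; see [autoplot.bp_agreement()].
#' @export
evaluate_cohort <- function(estimates = NULL, analysis = NULL, paired = NULL) {
  if (is.null(paired)) {
    if (is.null(estimates) || is.null(analysis)) {
      abort_param("supply `estimates` and `analysis`, or a `paired` tibble.")
    }
    refs <- analysis |>
      dplyr::filter(.data$session_label == "estimation_test") |>
      dplyr::select("subject_id", "resolved_sbp", "resolved_dbp")
    paired <- estimates |>
      dplyr::group_by(.data$subject_id, .data$model) |>
      dplyr::summarise(SBP = mean(.data$sbp_mmHg), DBP = mean(.data$dbp_mmHg),
                       .groups = "drop") |>
      dplyr::inner_join(refs, by = "subject_id") |>
      tidyr::pivot_longer(c("SBP", "DBP"), names_to = "pressure_type",
                          values_to = "estimate") |>
      dplyr::mutate(reference = ifelse(.data$pressure_type == "SBP",
                                       .data$resolved_sbp, .data$resolved_dbp)) |>
      dplyr::select("subject_id", "model", "pressure_type", "estimate", "reference")
  }
  if (nrow(paired) == 0) abort_param("no valid estimation sessions to evaluate.")
  report <- paired |>
    dplyr::group_by(.data$model, .data$pressure_type) |>
    dplyr::group_map(~ agreement_row(.x$estimate, .x$reference,
                                     .y$model, .y$pressure_type)) |>
    dplyr::bind_rows()
  structure(report, paired = paired, class = c("bp_agreement", class(report)))
}
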