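#' Construct a coefficient set for the estimation model
#'
#' The compensated model estimates blood pressure from a feature window as
#' `BP = a * PTT + b + c * VPTT + d * (PTTV - PTTV0)`, with PTT the mean of
#' the past `W` per-beat transit times in ms, VPTT the dimensionless
#' variation of that mean relative to the sitting reference, and PTTV the
#' window variability in ms. Units: `a` in mmHg/ms, `b` and `c` in mmHg
#' (`c` multiplies a dimensionless term), `d` in mmHg/ms. Systolic and
#' diastolic pressure carry fully independent coefficient sets.
#'
#' @param a,b,c,d Finite model coefficients (see above; `c = d = 0` reduces
#'   the model to the linear baseline `BP = a * PTT + b`).
#' @param pressure_type `"SBP"` or `"DBP"`.
#' @return One-row tibble with class `coefficient_set`.
#' @export
coefficient_set <- function(a, b, c = 0, d = 0, pressure_type = c("SBP", "DBP")) {
  pressure_type <- match.arg(pressure_type)
  vals <- c(a = a, b = b, c = c, d = d)
  if (!all(vapply(vals, is_scalar_number, logical(1)))) {
    abort_param("coefficients a, b, c, d must all be finite scalars.")
  }
  structure(tibble(pressure_type = pressure_type, a = a, b = b, c = c, d = d),
            class = c("coefficient_set", class(tibble())))
}

check_coefficients <- function(coeffs) {
  if (!is.data.frame(coeffs) || nrow(coeffs) != 1 ||
      !all(c("a", "b", "c", "d") %in% names(coeffs))) {
    abort_param("`coeffs` must be a one-row coefficient set with columns a, b, c, d.")
  }
  invisible(coeffs)
}

#' Estimate blood pressure with the compensated model
#'
#' Applies `BP = a * mean_PTT + b + c * VPTT + d * (PTTV - PTTV0)` to each
#' feature window. With `c = d = 0` this equals [estimate_bp_linear()]
#' exactly on every window.
#'
#' @param features Feature tibble from [rolling_features()] (columns
#'   `mean_ptt_ms`, `pttv_ms`, `vptt`) or a [session_summary()] row.
#' @param coeffs A [coefficient_set()].
#' @param reference The calibration reference supplying `PTTV0`.
#' @return `features` with an added `bp_mmHg` column.
#' @export
estimate_bp <- function(features, coeffs, reference) {
  check_coefficients(coeffs)
  check_reference(reference)
  if (!all(c("mean_ptt_ms", "pttv_ms", "vptt") %in% names(features))) {
    abort_param("`features` must have columns mean_ptt_ms, pttv_ms and vptt.")
  }
  dplyr::mutate(features,
                bp_mmHg = coeffs$a * .data$mean_ptt_ms + coeffs$b +
                  coeffs$c * .data$vptt +
                  coeffs$d * (.data$pttv_ms - reference$pttv0_ms))
}

#' Estimate blood pressure with the linear baseline
#'
#' The traditional linear PTT-BP mapping `BP = a * PTT + b`, applied to the
#' same windowed mean PTT as the compensated model so the two are directly
#' comparable.
#'
#' @inheritParams estimate_bp
#' @param a,b Linear coefficients (mmHg/ms and mmHg).
#' @return `features` with an added `bp_mmHg` column.
#' @export
estimate_bp_linear <- function(features, a, b) {
  if (!"mean_ptt_ms" %in% names(features)) {
    abort_param("`features` must have a mean_ptt_ms column.")
  }
  dplyr::mutate(features, bp_mmHg = a * .data$mean_ptt_ms + b)
}

#' Fit population coefficients by ordinary least squares
#'
#' Regresses reference blood pressure on the model design
#' `[mean_ptt_ms, 1, vptt, dpttv_ms]` over pooled data points (one per
#' subject-session by default in the pipeline; per-beat rows are equally
#' accepted). The fitted `c` and `d` are retained as population constants;
#' `a` and `b` are later personalised per subject by [calibrate_subject()].
#'
#' @param data Tibble with columns `mean_ptt_ms`, `vptt`,
#'   `dpttv_ms` (= PTTV minus the subject's PTTV0) and `bp_mmHg`.
#' @param pressure_type `"SBP"` or `"DBP"` (recorded in the result).
#' @return A `bp_population_fit` object; see [tidy()] and [glance()]
#'   methods. `$coefficients` is a [coefficient_set()].
#' @export
fit_population_coefficients <- function(data, pressure_type = c("SBP", "DBP")) {
  pressure_type <- match.arg(pressure_type)
  need <- c("mean_ptt_ms", "vptt", "dpttv_ms", "bp_mmHg")
  if (!all(need %in% names(data))) {
    abort_param(sprintf("`data` must have columns %s.", paste(need, collapse = ", ")))
  }
  if (nrow(data) < 4) abort_param("need at least 4 pooled data points to fit a, b, c, d.")
  fit <- lm(bp_mmHg ~ mean_ptt_ms + vptt + dpttv_ms, data = data)
  cf <- coef(fit)
  if (anyNA(cf)) {
    abort_param(sprintf(
      "rank-deficient design: no information to fit %s (column(s) collinear or constant).",
      paste(names(cf)[is.na(cf)], collapse = ", ")))
  }
  structure(list(coefficients = coefficient_set(a = unname(cf["mean_ptt_ms"]),
                                                b = unname(cf["(Intercept)"]),
                                                c = unname(cf["vptt"]),
                                                d = unname(cf["dpttv_ms"]),
                                                pressure_type = pressure_type),
                 fit = fit, pressure_type = pressure_type, n = nrow(data)),
            class = "bp_population_fit")
}

#' @export
print.bp_population_fit <- function(x, ...) {
  cat(sprintf("<bp_population_fit> %s on %d data points\n", x$pressure_type, x$n))
  print(x$coefficients)
  invisible(x)
}

#' @rdname fit_population_coefficients
#' @param x,object A `bp_population_fit`.
#' @param ... Unused.
#' @export
tidy.bp_population_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  map <- c("(Intercept)" = "b", "mean_ptt_ms" = "a", "vptt" = "c", "dpttv_ms" = "d")
  tibble(term = unname(map[rownames(s)]),
         estimate = unname(s[, "Estimate"]),
         std.error = unname(s[, "Std. Error"]),
         statistic = unname(s[, "t value"]),
         p.value = unname(s[, "Pr(>|t|)"])) |>
    dplyr::arrange(match(.data$term, c("a", "b", "c", "d")))
}

#' @rdname fit_population_coefficients
#' @export
glance.bp_population_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(pressure_type = x$pressure_type, r.squared = s$r.squared,
         adj.r.squared = s$adj.r.squared, sigma = s$sigma,
         nobs = x$n, df.residual = x$fit$df.residual)
}

#' Personalise a and b from the two calibration postures
#'
#' Solves the 2x2 linear system obtained by writing the compensated model at
#' the sitting and standing calibration points with the population `c` and
#' `d` held fixed. Because the sitting session defines the reference, its
#' equation reduces to `BP_sit = a * PTT_sit + b` exactly, so the fitted
#' line always interpolates the sitting calibration point. With
#' `c = d = 0` in `population` this is the calibration of the linear
#' baseline.
#'
#' @param sitting,standing One-row tibbles pairing the session's feature
#'   summary with its resolved reference pressure: columns `mean_ptt_ms`,
#'   `pttv_ms`, `vptt`, `bp_mmHg`.
#' @param population A [coefficient_set()] supplying `c` and `d`.
#' @param reference The subject's [session_reference()] (supplies `PTTV0`).
#' @param min_ptt_separation_ms Postures whose mean PTT differs by less than
#'   this (default 2 ms, below the 4 ms sample resolution at 250 Hz) make
#'   the system ill-conditioned and raise a degenerate-calibration error.
#' @return A [coefficient_set()] with personalised `a`, `b` and the
#'   population `c`, `d`.
#' @export
calibrate_subject <- function(sitting, standing, population, reference,
                              min_ptt_separation_ms = 2) {
  check_coefficients(population)
  check_reference(reference)
  need <- c("mean_ptt_ms", "pttv_ms", "vptt", "bp_mmHg")
  for (s in list(sitting, standing)) {
    if (!is.data.frame(s) || nrow(s) != 1 || !all(need %in% names(s))) {
      abort_param(sprintf("calibration points must be one-row tibbles with columns %s.",
                          paste(need, collapse = ", ")))
    }
  }
  d_ptt <- standing$mean_ptt_ms - sitting$mean_ptt_ms
  if (abs(d_ptt) < min_ptt_separation_ms) {
    abort(sprintf(
      "degenerate calibration: sitting and standing mean PTT differ by %.2f ms (< %g ms).",
      abs(d_ptt), min_ptt_separation_ms), class = "pttbp_degenerate_calibration")
  }
  comp <- function(s) population$c * s$vptt + population$d * (s$pttv_ms - reference$pttv0_ms)
  y_sit <- sitting$bp_mmHg - comp(sitting)
  y_sta <- standing$bp_mmHg - comp(standing)
  a <- (y_sta - y_sit) / d_ptt
  b <- y_sit - a * sitting$mean_ptt_ms
  coefficient_set(a = a, b = b, c = population$c, d = population$d,
                  pressure_type = population$pressure_type)
}

#' Construct a per-subject calibration profile
#'
#' Bundles a subject's calibration reference with the personalised
#' coefficient sets of both models (compensated and linear baseline) for
#' both pressure types.
#'
#' @param subject_id Subject identifier.
#' @param reference The subject's [session_reference()].
#' @param coefficients Tibble of coefficient rows with columns `model`
#'   (`"compensated"` or `"linear"`), `pressure_type`, `a`, `b`, `c`, `d`.
#' @return A `calibration_profile` object.
#' @export
calibration_profile <- function(subject_id, reference, coefficients) {
  check_reference(reference)
  need <- c("model", "pressure_type", "a", "b", "c", "d")
  if (!all(need %in% names(coefficients))) {
    abort_param(sprintf("`coefficients` must have columns %s.", paste(need, collapse = ", ")))
  }
  structure(list(subject_id = subject_id, reference = reference,
                 coefficients = as_tibble(coefficients)),
            class = "calibration_profile")
}

#' @export
print.calibration_profile <- function(x, ...) {
  cat(sprintf("<calibration_profile> subject %s (PTT0 = %.1f ms, PTTV0 = %.2f ms)\n",
              x$subject_id, x$reference$ptt0_ms, x$reference$pttv0_ms))
  print(x$coefficients)
  invisible(x)
}

profile_coeffs <- function(profile, model, pressure_type) {
  row <- dplyr::filter(profile$coefficients,
                       .data$model == !!model, .data$pressure_type == !!pressure_type)
  if (nrow(row) != 1) {
    abort_param(sprintf("profile for subject %s has no %s/%s coefficients.",
                        profile$subject_id, model, pressure_type))
  }
  row
}

#' Serialise / read a calibration profile (JSON)
#'
#' @param profile A [calibration_profile()].
#' @param path JSON file path.
#' @return `write_profile()` returns `path` invisibly; `read_profile()`
#'   returns the profile.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "calibration_profile"))
  jsonlite::write_json(
    list(schema_version = 1L,
         subject_id = profile$subject_id,
         reference = as.list(profile$reference[, c("ptt0_ms", "pttv0_ms")]),
         coefficients = profile$coefficients),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("profile not found: %s", path))
  p <- jsonlite::fromJSON(path)
  calibration_profile(p$subject_id,
                      tibble(ptt0_ms = p$reference$ptt0_ms, pttv0_ms = p$reference$pttv0_ms),
                      as_tibble(p$coefficients))
}

#' Estimate blood pressure over an estimation session
#'
#' Runs the full per-beat path over a processed session: rolling feature
#' windows against the subject's calibration reference, then the selected
#' model for both pressure types. Sessions failing the fluctuation validity
#' check are refused with the diagnostics in the error message.
#'
#' @param session Either a `session_analysis` row-list from
#'   [analyze_cohort()] (fields `ptt`, `validity`) or a PTT series tibble
#'   (assumed valid).
#' @param profile The subject's [calibration_profile()].
#' @param model `"compensated"` or `"linear"`.
#' @param rc A [run_config()] (supplies `W` and the PTTV convention).
#' @return Tibble of per-beat estimates: `beat`, `beat_time_s`, `model`,
#'   `sbp_mmHg`, `dbp_mmHg`, `pressure_order_ok` (FALSE flags the
#'   physiologically inconsistent case `dbp >= sbp`; the model output is
#'   unconstrained).
#' @export
estimate_session <- function(session, profile, model = c("compensated", "linear"),
                             rc = run_config()) {
  model <- match.arg(model)
  stopifnot(inherits(profile, "calibration_profile"))
  if (is.data.frame(session)) {
    ptt <- session
  } else {
    validity <- session$validity
    if (!is.null(validity) && !isTRUE(validity$valid)) {
      abort(sprintf("refusing to estimate an invalid session: %s", validity$reason),
            class = "pttbp_invalid_session")
    }
    ptt <- session$ptt
  }
  feats <- rolling_features(ptt, profile$reference, W = rc$W, pttv_window = rc$pttv_window)
  one <- function(type) {
    cf <- profile_coeffs(profile, model, type)
    if (model == "linear") {
      estimate_bp_linear(feats, cf$a, cf$b)$bp_mmHg
    } else {
      estimate_bp(feats, cf, profile$reference)$bp_mmHg
    }
  }
  out <- tibble(beat = feats$beat, beat_time_s = feats$beat_time_s, model = model,
                sbp_mmHg = one("SBP"), dbp_mmHg = one("DBP"))
  out$pressure_order_ok <- out$dbp_mmHg < out$sbp_mmHg
  if (nrow(out) && !all(out$pressure_order_ok)) {
    warn_validation(sprintf("%d beat(s) estimated with DBP >= SBP.",
                            sum(!out$pressure_order_ok)))
  }
  out
}
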