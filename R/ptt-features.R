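ptt_values <- function(ptt) {
  if (is.data.frame(ptt)) as.numeric(ptt$ptt_ms) else as.numeric(ptt)
}

#' PTT variability (PTTV) of a window
#'
#' PTTV is the sample standard deviation of the successive differences
#' (delta-PTT) of the PTT values in a short window; it is a surrogate for
#' autonomic (neural) regulation of the cardiovascular system. A window of
#' `W` PTT values yields `W - 1` differences, so the default 5-beat window
#' uses 4 differences with denominator 3. PTTV is zero for any arithmetic
#' progression of PTTs and invariant under adding a constant to the window.
#'
#' @param ptt_window_ms Numeric vector of at least 3 per-beat PTT values (ms).
#' @return PTTV in milliseconds (non-negative scalar).
#' @export
ptt_variability <- function(ptt_window_ms) {
  x <- ptt_values(ptt_window_ms)
  if (length(x) < 3) {
    abort_param("PTTV needs at least 3 PTT values (2 successive differences).")
  }
  sd(diff(x))
}

#' PTT variation (VPTT) relative to the calibration reference
#'
#' VPTT is the dimensionless relative deviation of PTT from the reference
#' `PTT0` established at the sitting calibration session:
#' `(PTT - PTT0) / PTT0`. It is sign-symmetric around `PTT0` and strictly
#' increasing in PTT.
#'
#' @param ptt_ms PTT value(s) in milliseconds (vectorised).
#' @param ptt0_ms Reference PTT in milliseconds (positive scalar).
#' @return Dimensionless variation, same length as `ptt_ms`.
#' @export
ptt_variation <- function(ptt_ms, ptt0_ms) {
  if (!is_scalar_number(ptt0_ms) || ptt0_ms <= 0) {
    abort_param("`ptt0_ms` must be a positive reference PTT.")
  }
  (as.numeric(ptt_ms) - ptt0_ms) / ptt0_ms
}

rolling_pttv <- function(x, pttv_window) {
  idx <- seq.int(pttv_window, length(x))
  vapply(idx, function(j) sd(diff(x[(j - pttv_window + 1L):j])), numeric(1))
}

#' Rolling per-beat feature windows
#'
#' Produces one feature row per beat once `W` beats have accumulated, using
#' the trailing `W` PTT values: their mean (`mean_ptt_ms`, the PTT value the
#' estimation model uses), their PTTV (`pttv_ms`) and the variation `vptt`
#' of the window mean relative to the calibration reference. With the
#' default convention the PTTV window equals `W`; the alternative
#' `pttv_window = W + 1` convention takes `W` differences from `W + 1`
#' values (see [run_config()]).
#'
#' @param ptt A PTT series tibble from [compute_ptt_series()] or a numeric
#'   vector of per-beat PTT values (ms).
#' @param reference Calibration reference from [session_reference()] (a
#'   one-row tibble with `ptt0_ms`, `pttv0_ms`).
#' @param W Number of past PTT measurements per window (default 5).
#' @param pttv_window Number of PTT values the PTTV term uses (default `W`).
#' @return Tibble with `max(0, n - max(W, pttv_window) + 1)` rows: `beat`,
#'   `beat_time_s`, `mean_ptt_ms`, `pttv_ms`, `vptt`. Empty (with a
#'   warning) when the series is shorter than a window.
#' @export
rolling_features <- function(ptt, reference, W = 5, pttv_window = W) {
  x <- ptt_values(ptt)
  times <- if (is.data.frame(ptt) && "beat_time_s" %in% names(ptt)) {
    ptt$beat_time_s
  } else {
    rep(NA_real_, length(x))
  }
  check_reference(reference)
  start <- max(W, pttv_window)
  empty <- tibble(beat = integer(0), beat_time_s = numeric(0),
                  mean_ptt_ms = numeric(0), pttv_ms = numeric(0), vptt = numeric(0))
  if (W < 2 || pttv_window < 3) abort_param("need W >= 2 and a PTTV window of >= 3 values.")
  if (length(x) < start) {
    warn_validation(sprintf("PTT series has %d beats; %d are needed for one window.",
                            length(x), start))
    return(empty)
  }
  idx <- seq.int(start, length(x))
  cs <- cumsum(c(0, x))
  mean_ptt <- (cs[idx + 1L] - cs[idx - W + 1L]) / W
  pttv <- vapply(idx, function(j) sd(diff(x[(j - pttv_window + 1L):j])), numeric(1))
  tibble(beat = idx,
         beat_time_s = times[idx],
         mean_ptt_ms = mean_ptt,
         pttv_ms = pttv,
         vptt = ptt_variation(mean_ptt, reference$ptt0_ms))
}

check_reference <- function(reference) {
  if (!is.data.frame(reference) ||
      !all(c("ptt0_ms", "pttv0_ms") %in% names(reference)) || nrow(reference) != 1) {
    abort_param("`reference` must be a one-row tibble with columns ptt0_ms and pttv0_ms.")
  }
  if (reference$ptt0_ms <= 0 || reference$pttv0_ms < 0) {
    abort_param("reference requires ptt0_ms > 0 and pttv0_ms >= 0.")
  }
  invisible(reference)
}

#' Calibration reference from the sitting session
#'
#' `PTT0` is the mean of all per-beat PTT values of the sitting calibration
#' session; `PTTV0` is the session-level PTTV, summarised as the arithmetic
#' mean of the rolling PTTV over all windows (the median is available via
#' `aggregate`).
#'
#' @inheritParams rolling_features
#' @param aggregate How rolling PTTV is summarised to the session level.
#' @return One-row tibble with `ptt0_ms`, `pttv0_ms`, `n_beats`.
#' @export
session_reference <- function(ptt, W = 5, pttv_window = W,
                              aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  x <- ptt_values(ptt)
  start <- max(W, pttv_window)
  if (length(x) < start) {
    abort_param(sprintf("insufficient beats for a calibration reference (%d < %d).",
                        length(x), start))
  }
  pttv <- rolling_pttv(x, pttv_window)
  agg <- if (aggregate == "mean") mean else median
  tibble(ptt0_ms = mean(x), pttv0_ms = agg(pttv), n_beats = length(x))
}

#' Session-level feature summary
#'
#' Summarises one session against a subject's calibration reference with the
#' same conventions used per beat: `mean_ptt_ms` is the mean of all per-beat
#' PTT values, `pttv_ms` the mean rolling PTTV, and `vptt` the variation of
#' the session mean relative to `PTT0`. By construction the sitting
#' calibration session summarised against its own reference has `vptt = 0`
#' and `pttv_ms` equal to `pttv0_ms` exactly.
#'
#' @inheritParams rolling_features
#' @return One-row tibble with `mean_ptt_ms`, `pttv_ms`, `vptt`, `n_beats`.
#' @export
session_summary <- function(ptt, reference, W = 5, pttv_window = W) {
  check_reference(reference)
  x <- ptt_values(ptt)
  start <- max(W, pttv_window)
  if (length(x) < start) {
    abort_param(sprintf("insufficient beats to summarise the session (%d < %d).",
                        length(x), start))
  }
  pttv <- rolling_pttv(x, pttv_window)
  m <- mean(x)
  tibble(mean_ptt_ms = m, pttv_ms = mean(pttv),
         vptt = ptt_variation(m, reference$ptt0_ms), n_beats = length(x))
}
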