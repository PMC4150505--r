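moving_window_samples <- function(window_ms, fs) {
  if (!is_scalar_number(window_ms) || window_ms <= 0) {
    abort_param("`window_ms` must be a positive duration in milliseconds.")
  }
  w <- window_ms * fs / 1000
  # nearest odd integer (ties round up) so the window is centred without
  # phase shift; a sub-sample duration degenerates to the identity window
  max(1L, 2L * as.integer(floor(w / 2)) + 1L)
}

#' Centred sliding-window (moving-average) filter
#'
#' Smooths a raw waveform with a centred moving average whose duration is
#' given in milliseconds (default 10 ms, i.e. 3 samples at 250 Hz after
#' rounding to the nearest odd window). Output length equals input length;
#' at the edges the window shrinks symmetrically, so a constant signal is
#' left unchanged everywhere and a 1-sample window is the identity.
#'
#' @param x Numeric amplitude vector.
#' @param fs Sampling rate in Hz.
#' @param window_ms Window duration in milliseconds.
#' @return Filtered numeric vector, same length as `x`.
#' @export
sliding_window_filter <- function(x, fs, window_ms = 10) {
  n <- length(x)
  w <- moving_window_samples(window_ms, fs)
  if (w > n) abort_param(sprintf("filter window (%d samples) is longer than the signal (%d).", w, n))
  if (w == 1L) return(as.numeric(x))
  h <- (w - 1L) %/% 2L
  i <- seq_len(n)
  k <- pmin(h, i - 1L, n - i)
  cs <- cumsum(c(0, as.numeric(x)))
  (cs[i + k + 1L] - cs[i - k]) / (2 * k + 1)
}

#' Detect ECG R-peaks
#'
#' Simplified Pan-Tompkins-style detector: the ECG is smoothed with the
#' sliding-window filter, a derivative-squared statistic is integrated over a
#' short energy window, and regions exceeding an adaptive threshold (running
#' median plus `threshold_k` times the MAD) are reduced to the local maximum
#' of the smoothed ECG. A refractory period removes physiologically
#' impossible double detections, and low-amplitude candidates (below
#' `amplitude_frac` of the median candidate amplitude) are rejected.
#'
#' @param ecg Numeric ECG amplitude vector (raw; smoothing is internal).
#' @param fs Sampling rate in Hz.
#' @param refractory_ms Minimum allowed interval between peaks (default 250 ms).
#' @param smooth_ms Pre-smoothing window (default 10 ms).
#' @param energy_ms Integration window for the derivative-squared energy.
#' @param threshold_k Threshold in MADs above the median energy.
#' @param amplitude_frac Reject candidates below this fraction of the median
#'   candidate amplitude.
#' @return Integer vector of ascending 1-based sample indices (sample `i`
#'   is at time `(i-1)/fs` seconds); empty with a warning when no peak is
#'   found.
#' @export
detect_r_peaks <- function(ecg, fs, refractory_ms = 250, smooth_ms = 10,
                           energy_ms = 120, threshold_k = 3, amplitude_frac = 0.4) {
  n <- length(ecg)
  if (n < 2L) {
    warn_validation("signal too short for R-peak detection; returning no peaks.")
    return(integer(0))
  }
  x <- sliding_window_filter(ecg, fs, min(smooth_ms, (n - 1) * 1000 / fs))
  e <- c(0, diff(x))^2
  E <- sliding_window_filter(e, fs, min(energy_ms, (n - 1) * 1000 / fs))
  thr <- max(median(E) + threshold_k * mad(E),
             1e-9 * max(E))  # floor absorbs cumsum float dust on silent stretches
  above <- E > thr
  if (!any(above)) {
    warn_validation("no R-peaks found (no region exceeds the detection threshold).")
    return(integer(0))
  }
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  pad <- as.integer(round(0.040 * fs))
  cand <- vapply(keep, function(g) {
    lo <- max(1L, starts[g] - pad)
    hi <- min(n, ends[g] + pad)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  cand <- sort(unique(cand))
  amp <- x[cand]
  cand <- cand[amp >= amplitude_frac * median(amp)]
  if (!length(cand)) {
    warn_validation("no R-peaks found after amplitude screening.")
    return(integer(0))
  }
  # refractory enforcement: keep the taller of any pair closer than the period
  refr <- round(refractory_ms / 1000 * fs)
  kept <- integer(0)
  for (j in order(x[cand], decreasing = TRUE)) {
    if (!length(kept) || all(abs(cand[j] - kept) >= refr)) kept <- c(kept, cand[j])
  }
  sort(kept)
}

#' Detect PPG pulse peaks and pair them with R-peaks
#'
#' For every consecutive pair of R-peaks, searches the physiologic transit
#' window (by default 100-600 ms after the R-peak, truncated at the next
#' R-peak so the pulse stays within the same cardiac cycle) for the maximum
#' of the smoothed PPG. The argmax is accepted only when it is an interior
#' local maximum; cycles whose PPG maximum falls on the window boundary (the
#' true pulse peak lies outside the physiologic window) stay unmatched.
#' Ties take the earliest sample. Pairing is injective by construction: one
#' cycle yields at most one pair.
#'
#' @param ppg Numeric PPG amplitude vector (raw; smoothing is internal).
#' @param fs Sampling rate in Hz.
#' @param r_peaks Ascending R-peak sample indices from [detect_r_peaks()].
#' @param smooth_ms Pre-smoothing window (default 10 ms).
#' @param min_delay_ms,max_delay_ms Bounds of the transit search window.
#' @return A `beat_annotations` list with elements `r_peaks`, `ppg_peaks`,
#'   `pairs` (tibble `r_index`, `ppg_index`), `n_cycles` (number of complete
#'   cardiac cycles, i.e. R-peak pairs) and `fs`.
#' @export
detect_ppg_peaks <- function(ppg, fs, r_peaks, smooth_ms = 10,
                             min_delay_ms = 100, max_delay_ms = 600) {
  r_peaks <- as.integer(r_peaks)
  if (is.unsorted(r_peaks, strictly = TRUE)) abort_param("`r_peaks` must be strictly increasing.")
  ann <- function(pairs) {
    structure(list(r_peaks = r_peaks,
                   ppg_peaks = pairs$ppg_index,
                   pairs = pairs,
                   n_cycles = max(0L, length(r_peaks) - 1L),
                   fs = fs),
              class = "beat_annotations")
  }
  empty <- tibble(r_index = integer(0), ppg_index = integer(0))
  if (length(r_peaks) < 2L) {
    warn_validation("fewer than 2 R-peaks: no cardiac cycle to search for PPG pulses.")
    return(ann(empty))
  }
  n <- length(ppg)
  x <- sliding_window_filter(ppg, fs, smooth_ms)
  min_s <- as.integer(round(min_delay_ms / 1000 * fs))
  max_s <- as.integer(round(max_delay_ms / 1000 * fs))
  out_r <- integer(0); out_p <- integer(0)
  for (i in seq_len(length(r_peaks) - 1L)) {
    lo <- r_peaks[i] + min_s + 1L        # strictly more than min_delay after R
    hi <- min(r_peaks[i] + max_s, r_peaks[i + 1L] - 1L, n)
    if (hi < lo) next
    p <- lo + which.max(x[lo:hi]) - 1L
    if (p <= 1L || p >= n) next
    if (!(x[p] >= x[p - 1L] && x[p] > x[p + 1L])) next  # boundary/monotone window
    out_r <- c(out_r, r_peaks[i]); out_p <- c(out_p, p)
  }
  ann(tibble(r_index = out_r, ppg_index = out_p))
}

#' @export
print.beat_annotations <- function(x, ...) {
  cat(sprintf("<beat_annotations> %d R-peaks, %d matched PPG pulses over %d cycles (fs = %g Hz)\n",
              length(x$r_peaks), nrow(x$pairs), x$n_cycles, x$fs))
  invisible(x)
}

#' Detect beats on a waveform record
#'
#' Convenience wrapper running [detect_r_peaks()] on the ECG channel and
#' [detect_ppg_peaks()] on the PPG channel of a [waveform_record()].
#'
#' @param record A [waveform_record()].
#' @param smooth_ms Smoothing window passed to both detectors.
#' @param ... Further arguments to [detect_r_peaks()].
#' @return A `beat_annotations` object.
#' @export
detect_beats <- function(record, smooth_ms = 10, ...) {
  stopifnot(inherits(record, "waveform_record"))
  fs <- record_fs(record)
  r <- detect_r_peaks(record$ecg, fs, smooth_ms = smooth_ms, ...)
  detect_ppg_peaks(record$ppg, fs, r, smooth_ms = smooth_ms)
}

#' Compute the beat-to-beat PTT series
#'
#' PTT for a matched beat is the interval from the ECG R-peak to the PPG
#' pulse peak of the same cardiac cycle, in milliseconds.
#'
#' @param annotations A `beat_annotations` object from [detect_ppg_peaks()]
#'   or [detect_beats()].
#' @param fs Sampling rate in Hz (defaults to the annotations' rate).
#' @return A tibble with one row per matched beat: `beat`, `r_index`,
#'   `ppg_index`, `beat_time_s` (time of the R-peak), `ptt_ms` and
#'   `delta_ms` (successive difference, `NA` for the first beat). Empty
#'   when there are no matched pairs.
#' @export
compute_ptt_series <- function(annotations, fs = annotations$fs) {
  stopifnot(inherits(annotations, "beat_annotations"))
  pr <- annotations$pairs
  out <- tibble(beat = seq_len(nrow(pr)),
                r_index = pr$r_index,
                ppg_index = pr$ppg_index,
                beat_time_s = (pr$r_index - 1) / fs,
                ptt_ms = (pr$ppg_index - pr$r_index) * 1000 / fs)
  out$delta_ms <- c(NA_real_, diff(out$ptt_ms))
  structure(out, n_cycles = annotations$n_cycles, fs = fs,
            class = c("ptt_series", class(out)))
}

#' Signal-fluctuation validity check
#'
#' A recording with large PTT fluctuation indicates unstable physiology or
#' measurement artefact and is rejected. The default rule flags a session
#' invalid when the PTT coefficient of variation exceeds `cv_threshold`,
#' when more than `max_unmatched_frac` of the cardiac cycles yielded no
#' matched pulse, or when fewer than `min_beats` beats are available.
#'
#' @param ptt A PTT series tibble from [compute_ptt_series()] or a numeric
#'   vector of per-beat PTT values in ms.
#' @param n_cycles Number of complete cardiac cycles (taken from the series
#'   attribute when available) used for the unmatched fraction.
#' @param cv_threshold Maximum allowed coefficient of variation (default 0.2).
#' @param max_unmatched_frac Maximum allowed fraction of unmatched cycles.
#' @param min_beats Minimum number of beats required (default 10).
#' @return One-row tibble: `valid`, `n_beats`, `cv`, `unmatched_frac`,
#'   `reason` (`NA` when valid).
#' @export
check_signal_fluctuation <- function(ptt, n_cycles = NULL, cv_threshold = 0.2,
                                     max_unmatched_frac = 0.2, min_beats = 10) {
  if (is.data.frame(ptt)) {
    n_cycles <- n_cycles %||% attr(ptt, "n_cycles")
    ptt <- ptt$ptt_ms
  }
  n <- length(ptt)
  cv <- if (n >= 2 && mean(ptt) > 0) sd(ptt) / mean(ptt) else NA_real_
  unmatched <- if (!is.null(n_cycles) && n_cycles > 0) 1 - n / n_cycles else NA_real_
  reason <- NA_character_
  if (n < min_beats) {
    reason <- "insufficient beats"
  } else if (!is.na(cv) && cv > cv_threshold) {
    reason <- sprintf("PTT coefficient of variation %.3f exceeds %.3f", cv, cv_threshold)
  } else if (!is.na(unmatched) && unmatched > max_unmatched_frac) {
    reason <- sprintf("%.0f%% of cardiac cycles unmatched (limit %.0f%%)",
                      100 * unmatched, 100 * max_unmatched_frac)
  }
  tibble(valid = is.na(reason), n_beats = n, cv = cv,
         unmatched_frac = unmatched, reason = reason)
}
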