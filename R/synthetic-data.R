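#' Per-subject ground-truth law for the synthetic cohort
#'
#' A subject law fixes everything the generator needs to emit coupled
#' PTT/BP truth for one subject: the true coefficient sets of the
#' compensated model for both pressure types, the subject's baseline PTT,
#' the hydrostatic posture shift (standing minus sitting), the
#' low-frequency PTT oscillation (Mayer-wave band), beat-to-beat jitter and
#' heart rate.
#'
#' @param coeffs Tibble with columns `pressure_type`, `a`, `b`, `c`, `d`
#'   (one row per pressure type) — the subject's true model law.
#' @param baseline_ptt_ms Sitting baseline PTT (ms, > 0).
#' @param posture_ptt_shift_ms Standing-minus-sitting PTT shift (ms).
#' @param lf_variability_amp_ms,lf_period_s Low-frequency PTT oscillation
#'   amplitude (ms) and period (s).
#' @param ptt_jitter_sd_ms White beat-to-beat PTT jitter SD (ms).
#' @param heart_rate_bpm Heart rate in beats per minute (40-180).
#' @param hr_jitter_cv Coefficient of variation of the beat interval.
#' @param bp_noise_sd_mmHg Per-beat Gaussian noise SD added to the true BP.
#' @param subject_id Identifier.
#' @return A `subject_law` list.
#' @export
subject_law <- function(coeffs,
                        baseline_ptt_ms = 200,
                        posture_ptt_shift_ms = -15,
                        lf_variability_amp_ms = 5,
                        lf_period_s = 10,
                        ptt_jitter_sd_ms = 2,
                        heart_rate_bpm = 70,
                        hr_jitter_cv = 0.03,
                        bp_noise_sd_mmHg = 0,
                        subject_id = "S01") {
  if (baseline_ptt_ms <= 0) abort_param("`baseline_ptt_ms` must be positive.")
  if (heart_rate_bpm < 40 || heart_rate_bpm > 180) {
    abort_param("`heart_rate_bpm` must lie in [40, 180].")
  }
  if (lf_variability_amp_ms < 0 || ptt_jitter_sd_ms < 0 || bp_noise_sd_mmHg < 0) {
    abort_param("amplitudes and noise SDs must be non-negative.")
  }
  if (!all(c("SBP", "DBP") %in% coeffs$pressure_type)) {
    abort_param("`coeffs` must carry one row per pressure type (SBP and DBP).")
  }
  structure(list(coeffs = as_tibble(coeffs),
                 baseline_ptt_ms = baseline_ptt_ms,
                 posture_ptt_shift_ms = posture_ptt_shift_ms,
                 lf_variability_amp_ms = lf_variability_amp_ms,
                 lf_period_s = lf_period_s,
                 ptt_jitter_sd_ms = ptt_jitter_sd_ms,
                 heart_rate_bpm = heart_rate_bpm,
                 hr_jitter_cv = hr_jitter_cv,
                 bp_noise_sd_mmHg = bp_noise_sd_mmHg,
                 subject_id = subject_id),
            class = "subject_law")
}

law_coeffs <- function(law, type) {
  dplyr::filter(law$coeffs, .data$pressure_type == !!type)
}

#' Cohort generator configuration
#'
#' The generator's defaults define the emulated study conditions: a cohort
#' of healthy young adults measured at 250 Hz in three 3-minute sessions
#' (sitting calibration, standing calibration, sitting estimation test)
#' with oscillometric reference measurements per session. Population
#' spreads and the compensation constants are documented in the methods
#' vignette; all are configurable.
#'
#' @param duration_s Recording duration per session (s; protocol records
#'   3 minutes).
#' @param fs Sampling rate (Hz).
#' @param W Feature window length in beats.
#' @param pttv_window PTT count per PTTV window (default `W`).
#' @param baseline_ptt_mean_ms,baseline_ptt_sd_ms Between-subject baseline
#'   PTT distribution (clipped to \[130, 320\] ms).
#' @param posture_ptt_shift_ms Standing-minus-sitting PTT shift (ms).
#' @param lf_amp_ms,lf_period_s Low-frequency PTT oscillation (Mayer-wave
#'   band) amplitude and period.
#' @param standing_lf_scale Multiplier on LF amplitude while standing
#'   (sympathetic activation raises LF variability upright).
#' @param ptt_jitter_sd_ms White beat-to-beat PTT jitter SD.
#' @param hr_mean_bpm,hr_sd_bpm Heart-rate distribution (clipped \[50, 100\]).
#' @param hr_jitter_cv Beat-interval jitter CV.
#' @param sbp0_mean,sbp0_sd,dbp0_mean,dbp0_sd Resting sitting blood
#'   pressure distributions (mmHg).
#' @param a_sbp_mean,a_sbp_sd,a_dbp_mean,a_dbp_sd Per-subject PTT slope
#'   distributions (mmHg/ms).
#' @param c_sbp,d_sbp,c_dbp,d_dbp Population compensation constants
#'   (mmHg and mmHg/ms).
#' @param shared_coefficients When TRUE every subject receives the identical
#'   coefficient set (`a` at its mean, common `b`); used for parameter
#'   recovery experiments where the population regression must be exactly
#'   specified.
#' @param test_ptt_offset_sd_ms SD of the session-to-session baseline PTT
#'   offset of the estimation-test session (blood pressure drifts between
#'   calibration and test; this is what the variation term compensates).
#' @param test_variability_log_sd Log-SD of the estimation-test session's
#'   LF-amplitude and jitter scaling (variability state differs at test
#'   time; this is what the variability term compensates).
#' @param bp_noise_sd Per-beat Gaussian BP noise SD (mmHg).
#' @param osc_noise_sd Oscillometer measurement noise SD (mmHg).
#' @param ecg_noise_sd,ppg_noise_sd Additive white noise on the rendered
#'   waveforms (amplitude units; peaks have unit amplitude).
#' @param fluctuation_subjects Integer indices of subjects whose
#'   estimation-test session receives a programmed measurement-artifact
#'   burst (PTT jitter with SD `fluct_artifact_rel` times the subject's
#'   baseline PTT), exercising the data-rejection rule.
#' @param fluct_artifact_rel Relative artifact SD for burst subjects.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(duration_s = 180, fs = 250, W = 5, pttv_window = W,
                          baseline_ptt_mean_ms = 200, baseline_ptt_sd_ms = 45,
                          posture_ptt_shift_ms = -15,
                          lf_amp_ms = 5, lf_period_s = 10, standing_lf_scale = 1.4,
                          ptt_jitter_sd_ms = 2,
                          hr_mean_bpm = 70, hr_sd_bpm = 8, hr_jitter_cv = 0.03,
                          sbp0_mean = 115, sbp0_sd = 8,
                          dbp0_mean = 72, dbp0_sd = 6,
                          a_sbp_mean = -0.45, a_sbp_sd = 0.06,
                          a_dbp_mean = -0.15, a_dbp_sd = 0.04,
                          c_sbp = -40, d_sbp = 0.8,
                          c_dbp = -60, d_dbp = 3.5,
                          shared_coefficients = FALSE,
                          test_ptt_offset_sd_ms = 8,
                          test_variability_log_sd = 0.35,
                          bp_noise_sd = 2, osc_noise_sd = 2,
                          ecg_noise_sd = 0.02, ppg_noise_sd = 0.002,
                          fluctuation_subjects = integer(0),
                          fluct_artifact_rel = 0.35) {
  cfg <- as.list(environment())
  structure(cfg, class = "cohort_config")
}

#' Remove all stochastic observation noise from a cohort config
#'
#' Zeroes per-beat BP noise, oscillometer noise and waveform noise (the
#' physiological PTT dynamics — LF oscillation, beat jitter, posture shift —
#' remain). Under a noise-free config the rendered waveforms determine the
#' quantized truth exactly, so the full pipeline inverts the generator up
#' to sample quantization.
#'
#' @param config A [cohort_config()].
#' @return The modified config.
#' @export
config_noise_free <- function(config = cohort_config()) {
  config$bp_noise_sd <- 0
  config$osc_noise_sd <- 0
  config$ecg_noise_sd <- 0
  config$ppg_noise_sd <- 0
  config
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

draw_subject_law <- function(config, i) {
  ptt0 <- clip(rnorm(1, config$baseline_ptt_mean_ms, config$baseline_ptt_sd_ms), 130, 320)
  hr <- clip(rnorm(1, config$hr_mean_bpm, config$hr_sd_bpm), 50, 100)
  if (config$shared_coefficients) {
    a_s <- config$a_sbp_mean
    a_d <- config$a_dbp_mean
    b_s <- config$sbp0_mean - a_s * config$baseline_ptt_mean_ms
    b_d <- config$dbp0_mean - a_d * config$baseline_ptt_mean_ms
  } else {
    a_s <- min(rnorm(1, config$a_sbp_mean, config$a_sbp_sd), -0.05)
    a_d <- min(rnorm(1, config$a_dbp_mean, config$a_dbp_sd), -0.02)
    sbp0 <- rnorm(1, config$sbp0_mean, config$sbp0_sd)
    dbp0 <- min(rnorm(1, config$dbp0_mean, config$dbp0_sd), sbp0 - 25)
    b_s <- sbp0 - a_s * ptt0
    b_d <- dbp0 - a_d * ptt0
  }
  subject_law(
    coeffs = tibble(pressure_type = c("SBP", "DBP"),
                    a = c(a_s, a_d), b = c(b_s, b_d),
                    c = c(config$c_sbp, config$c_dbp),
                    d = c(config$d_sbp, config$d_dbp)),
    baseline_ptt_ms = ptt0,
    posture_ptt_shift_ms = config$posture_ptt_shift_ms,
    lf_variability_amp_ms = config$lf_amp_ms,
    lf_period_s = config$lf_period_s,
    ptt_jitter_sd_ms = config$ptt_jitter_sd_ms,
    heart_rate_bpm = hr,
    hr_jitter_cv = config$hr_jitter_cv,
    bp_noise_sd_mmHg = config$bp_noise_sd,
    subject_id = sprintf("S%02d", i))
}

#' Generate one session's beat-level ground truth
#'
#' Beat times follow the subject's heart rate with multiplicative interval
#' jitter; per-beat PTT is baseline plus posture shift plus a sinusoidal
#' low-frequency oscillation plus white jitter, quantized to the sampling
#' grid (the truth is defined on the grid the waveforms are rendered on, so
#' peak detection can recover it exactly). Per-beat blood pressure follows
#' the subject's own compensated-model law evaluated on the rolling
#' VPTT/PTTV features of the true PTT sequence — the same windowing code the
#' estimation pipeline uses — plus optional white noise. The last beat is
#' flagged non-measurable: its pulse peak has no following R-wave to close
#' the cardiac cycle, so no detector can time it.
#'
#' @param law A [subject_law()].
#' @param posture `"sitting"` or `"standing"`.
#' @param duration_s Session duration in seconds (>= 30).
#' @param fs Sampling rate (Hz, >= 100).
#' @param seed Optional integer seed (identical seeds give identical
#'   tables); `NULL` uses the ambient RNG stream.
#' @param reference Calibration reference ([session_reference()] shape)
#'   the law's VPTT/PTTV terms are evaluated against; `NULL` derives it
#'   from this session's own PTT sequence (appropriate for the sitting
#'   calibration session, which defines the reference).
#' @param lf_scale,jitter_scale Session-level multipliers on LF amplitude
#'   and beat jitter.
#' @param ptt_offset_ms Session-level baseline PTT offset (ms).
#' @param artifact_jitter_sd_ms SD of a measurement-artifact jitter added to
#'   the recorded PTT after the physiological law is evaluated: the rendered
#'   pulse timing fluctuates but blood pressure does not follow it
#'   (emulating sensor artefact / unstable recordings that the fluctuation
#'   check must reject).
#' @param W,pttv_window Feature window conventions (as in
#'   [rolling_features()]).
#' @return A `truth_table` tibble: `beat`, `r_sample` (0-based grid index),
#'   `r_time_s`, `ptt_ms` (grid-quantized), `measurable`, `true_sbp_mmHg`,
#'   `true_dbp_mmHg` (NA until a full window accumulates), `posture`.
#'   Attributes: `fs`, `duration_s`, `reference`, `session_bp` (noise-free
#'   session-level true BP per pressure type, the subject's law applied to
#'   the session feature summary), `subject_id`.
#' @export
generate_beat_sequence <- function(law, posture = c("sitting", "standing"),
                                   duration_s = 180, fs = 250, seed = NULL,
                                   reference = NULL, lf_scale = 1, jitter_scale = 1,
                                   ptt_offset_ms = 0, artifact_jitter_sd_ms = 0,
                                   W = 5, pttv_window = W) {
  posture <- match.arg(posture)
  stopifnot(inherits(law, "subject_law"))
  if (duration_s < 30) abort_param("`duration_s` must be at least 30 s.")
  if (fs < 100) abort_param("`fs` must be at least 100 Hz.")
  maybe_with_seed(seed, {
    base_iv <- 60 / law$heart_rate_bpm
    n_max <- ceiling(duration_s / base_iv) + 8L
    iv <- base_iv * (1 + rnorm(n_max, 0, law$hr_jitter_cv))
    iv <- pmax(iv, 0.3)
    t_beat <- 0.5 + cumsum(iv) - iv[1]
    t_beat <- t_beat[t_beat <= duration_s - 1.2]
    B <- length(t_beat)
    if (B < max(W, pttv_window) + 2L) abort_param("session too short for a feature window.")
    r_sample <- as.integer(round(t_beat * fs))
    # grid rounding must preserve strict ordering (intervals >> 1 sample)
    stopifnot(!is.unsorted(r_sample, strictly = TRUE))
    shift <- if (posture == "standing") law$posture_ptt_shift_ms else 0
    phase <- runif(1, 0, 2 * pi)
    ptt_raw <- law$baseline_ptt_ms + shift + ptt_offset_ms +
      law$lf_variability_amp_ms * lf_scale * sin(2 * pi * t_beat / law$lf_period_s + phase) +
      rnorm(B, 0, law$ptt_jitter_sd_ms * jitter_scale)
    gap_ms <- c(diff(r_sample), Inf) * 1000 / fs
    ptt_raw <- clip(ptt_raw, 120, pmin(580, gap_ms - 2000 / fs))
    ptt_q <- round(ptt_raw * fs / 1000) * 1000 / fs
    measurable <- c(rep(TRUE, B - 1L), FALSE)
    x <- ptt_q[measurable]
    if (is.null(reference)) {
      reference <- session_reference(x, W = W, pttv_window = pttv_window)
    }
    feats <- rolling_features(x, reference, W = W, pttv_window = pttv_window)
    summ <- session_summary(x, reference, W = W, pttv_window = pttv_window)
    bp_col <- function(type) {
      cf <- law_coeffs(law, type)
      out <- rep(NA_real_, B)
      clean <- cf$a * feats$mean_ptt_ms + cf$b + cf$c * feats$vptt +
        cf$d * (feats$pttv_ms - reference$pttv0_ms)
      out[feats$beat] <- clean + rnorm(nrow(feats), 0, law$bp_noise_sd_mmHg)
      out
    }
    session_bp <- tibble(
      pressure_type = c("SBP", "DBP"),
      bp_mmHg = vapply(c("SBP", "DBP"), function(type) {
        cf <- law_coeffs(law, type)
        cf$a * summ$mean_ptt_ms + cf$b + cf$c * summ$vptt +
          cf$d * (summ$pttv_ms - reference$pttv0_ms)
      }, numeric(1)))
    if (artifact_jitter_sd_ms > 0) {
      # artefact corrupts the recorded pulse timing only; BP above follows
      # the clean physiological PTT
      art <- clip(ptt_q + rnorm(B, 0, artifact_jitter_sd_ms),
                  120, pmin(580, gap_ms - 2000 / fs))
      ptt_q <- round(art * fs / 1000) * 1000 / fs
    }
    truth <- tibble(beat = seq_len(B),
                    r_sample = r_sample,
                    r_time_s = r_sample / fs,
                    ptt_ms = ptt_q,
                    measurable = measurable,
                    true_sbp_mmHg = bp_col("SBP"),
                    true_dbp_mmHg = bp_col("DBP"),
                    posture = posture)
    structure(truth, fs = fs, duration_s = duration_s, reference = reference,
              session_bp = session_bp, subject_id = law$subject_id,
              class = c("truth_table", class(truth)))
  })
}

#' Render ECG/PPG waveforms from a truth table
#'
#' ECG R-waves are rendered as narrow Gaussian bumps (SD 10 ms, unit
#' amplitude) at the beat samples; PPG pulses as raised-cosine bumps
#' (full width 300 ms, unit amplitude) whose maxima lie exactly at
#' `r_sample + PTT` on the sample grid. Optional white Gaussian noise is
#' added per channel.
#'
#' @param truth A `truth_table` from [generate_beat_sequence()].
#' @param fs Sampling rate (defaults to the truth table's).
#' @param ecg_noise_sd,ppg_noise_sd Additive noise SD per channel
#'   (amplitude units).
#' @param seed Optional seed for the noise draw.
#' @param ecg_width_ms,ppg_width_ms Morphology widths (Gaussian SD; full
#'   raised-cosine width).
#' @return A [waveform_record()].
#' @export
render_waveforms <- function(truth, fs = attr(truth, "fs"),
                             ecg_noise_sd = 0, ppg_noise_sd = 0, seed = NULL,
                             ecg_width_ms = 10, ppg_width_ms = 300) {
  stopifnot(inherits(truth, "truth_table"))
  duration_s <- attr(truth, "duration_s")
  n <- as.integer(round(duration_s * fs))
  centers <- truth$r_sample + 1L                     # 1-based storage index
  ptt_samples <- as.integer(round(truth$ptt_ms * fs / 1000))
  ppg_centers <- centers + ptt_samples
  nxt <- c(centers[-1], Inf)
  if (any(ppg_centers >= nxt)) {
    abort("PTT longer than the beat interval: a pulse peak would leave its cardiac cycle.",
          class = "pttbp_generation_error")
  }
  ecg <- numeric(n)
  ppg <- numeric(n)
  sd_samp <- ecg_width_ms / 1000 * fs
  half_ecg <- as.integer(ceiling(5 * sd_samp))
  half_ppg_s <- ppg_width_ms / 2000 * fs
  half_ppg <- as.integer(floor(half_ppg_s))
  for (i in seq_len(nrow(truth))) {
    j <- max(1L, centers[i] - half_ecg):min(n, centers[i] + half_ecg)
    ecg[j] <- ecg[j] + exp(-0.5 * ((j - centers[i]) / sd_samp)^2)
    p <- ppg_centers[i]
    j <- max(1L, p - half_ppg):min(n, p + half_ppg)
    ppg[j] <- ppg[j] + 0.5 * (1 + cos(pi * (j - p) / half_ppg_s))
  }
  maybe_with_seed(seed, {
    if (ecg_noise_sd > 0) ecg <- ecg + rnorm(n, 0, ecg_noise_sd)
    if (ppg_noise_sd > 0) ppg <- ppg + rnorm(n, 0, ppg_noise_sd)
    waveform_record(ecg, ppg, fs = fs,
                    subject_id = attr(truth, "subject_id"),
                    posture = truth$posture[1])
  })
}

#' Noise SD achieving a target signal-to-noise ratio
#'
#' @param signal Clean signal vector.
#' @param snr_db Target SNR in dB (signal power over noise power).
#' @return White-noise standard deviation.
#' @export
snr_noise_sd <- function(signal, snr_db) {
  sqrt(mean(signal^2)) / 10^(snr_db / 20)
}

draw_measurements <- function(session_bp, osc_noise_sd) {
  truth <- setNames(session_bp$bp_mmHg, session_bp$pressure_type)
  m <- function() truth + rnorm(2, 0, osc_noise_sd)
  m1 <- m(); m2 <- m()
  meas <- tibble(order_index = 1:2,
                 sbp = c(m1["SBP"], m2["SBP"]),
                 dbp = c(m1["DBP"], m2["DBP"]))
  diffs <- abs(m1 - m2)
  if (any(diffs >= 5 & diffs <= 10) && all(diffs <= 10)) {
    m3 <- m()
    meas <- dplyr::bind_rows(meas, tibble(order_index = 3L,
                                          sbp = m3[["SBP"]], dbp = m3[["DBP"]]))
  }
  meas
}

#' Simulate a synthetic cohort in memory
#'
#' Draws per-subject laws from the configured population, generates the
#' three protocol sessions per subject (sitting calibration defines the
#' reference; standing calibration carries the hydrostatic shift and raised
#' LF variability; the estimation-test session receives a session-level
#' baseline offset and variability rescaling), renders waveforms and draws
#' the duplicated oscillometric reference measurements per the protocol.
#' All output is a pure function of `(config, seed)`.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @param render Render ECG/PPG waveforms (TRUE for pipeline use; FALSE
#'   keeps only beat-level truth, e.g. for regression experiments on the
#'   truth tables).
#' @return A `ptt_cohort` list: `subjects` (each with `law`, `reference`,
#'   and three `sessions` holding `truth`, `record` (if rendered) and
#'   `measurements`), plus `config` and `seed`.
#' @export
simulate_cohort <- function(n_subjects, config = cohort_config(), seed = NULL,
                            render = TRUE) {
  if (n_subjects < 1) abort_param("`n_subjects` must be at least 1.")
  maybe_with_seed(seed, {
    subjects <- purrr::map(seq_len(n_subjects), function(i) {
      law <- draw_subject_law(config, i)
      sit <- generate_beat_sequence(law, "sitting", config$duration_s, config$fs,
                                    W = config$W, pttv_window = config$pttv_window)
      reference <- attr(sit, "reference")
      sta <- generate_beat_sequence(law, "standing", config$duration_s, config$fs,
                                    reference = reference,
                                    lf_scale = config$standing_lf_scale,
                                    W = config$W, pttv_window = config$pttv_window)
      burst <- i %in% config$fluctuation_subjects
      test <- generate_beat_sequence(
        law, "sitting", config$duration_s, config$fs,
        reference = reference,
        lf_scale = exp(rnorm(1, 0, config$test_variability_log_sd)),
        jitter_scale = exp(rnorm(1, 0, config$test_variability_log_sd)),
        ptt_offset_ms = rnorm(1, 0, config$test_ptt_offset_sd_ms),
        artifact_jitter_sd_ms = if (burst) {
          config$fluct_artifact_rel * law$baseline_ptt_ms
        } else 0,
        W = config$W, pttv_window = config$pttv_window)
      truths <- list(calibration_sitting = sit,
                     calibration_standing = sta,
                     estimation_test = test)
      sessions <- purrr::imap(truths, function(truth, label) {
        rec <- if (render) {
          render_waveforms(truth, ecg_noise_sd = config$ecg_noise_sd,
                           ppg_noise_sd = config$ppg_noise_sd)
        }
        if (!is.null(rec)) {
          attr(rec, "session_label") <- label
          attr(rec, "subject_id") <- law$subject_id
        }
        list(session_label = label,
             posture = truth$posture[1],
             truth = truth,
             record = rec,
             measurements = draw_measurements(attr(truth, "session_bp"),
                                              config$osc_noise_sd),
             session_bp = attr(truth, "session_bp"))
      })
      list(subject_id = law$subject_id, law = law, reference = reference,
           sessions = sessions)
    })
    structure(list(subjects = subjects, config = config, seed = seed),
              class = "ptt_cohort")
  })
}

#' @export
print.ptt_cohort <- function(x, ...) {
  cat(sprintf("<ptt_cohort> %d subjects x 3 sessions (%g s at %g Hz)\n",
              length(x$subjects), x$config$duration_s, x$config$fs))
  invisible(x)
}

#' Generate a synthetic cohort on disk
#'
#' Wraps [simulate_cohort()] and writes, under `out_dir`: one waveform CSV
#' per session, beat-level truth tables under `truth/` (for assertions, not
#' consumed by the pipeline) and an `experiment.json` config consumable by
#' [load_experiment_config()]. Identical seeds yield identical trees.
#'
#' @inheritParams simulate_cohort
#' @param out_dir Output directory; must be empty unless `overwrite`.
#' @param overwrite Allow writing into a non-empty directory.
#' @return Invisibly, a list with `dir`, `config_path`, `sessions` (tibble
#'   of written paths) and the in-memory `cohort`.
#' @export
generate_cohort <- function(n_subjects, out_dir, config = cohort_config(),
                            seed = NULL, overwrite = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite) {
    abort_config(sprintf("output directory %s is not empty (use overwrite = TRUE).", out_dir))
  }
  dir.create(file.path(out_dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(n_subjects, config, seed, render = TRUE)
  rows <- purrr::map_dfr(cohort$subjects, function(subj) {
    purrr::map_dfr(subj$sessions, function(ss) {
      fname <- sprintf("%s_%s.csv", subj$subject_id, ss$session_label)
      write_waveform(ss$record, file.path(out_dir, fname))
      readr::write_csv(as_tibble(ss$truth),
                       file.path(out_dir, "truth",
                                 sprintf("%s_%s_truth.csv", subj$subject_id, ss$session_label)),
                       progress = FALSE)
      tibble(subject_id = subj$subject_id, session_label = ss$session_label,
             posture = ss$posture, waveform_path = fname,
             measurements = list(ss$measurements))
    })
  })
  config_path <- file.path(out_dir, "experiment.json")
  write_experiment_config(rows, config_path, fs = config$fs)
  invisible(list(dir = out_dir, config_path = config_path,
                 sessions = rows, cohort = cohort))
}
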