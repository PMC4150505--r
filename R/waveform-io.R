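#' Session labels recognised by the experiment protocol
#'
#' The protocol records three data sessions per subject: a sitting and a
#' standing calibration session (used to personalise the model) and one
#' estimation-test session (used to evaluate it).
#'
#' @export
SESSION_LABELS <- c("calibration_sitting", "calibration_standing", "estimation_test")

default_posture <- function(session_label) {
  c(calibration_sitting = "sitting",
    calibration_standing = "standing",
    estimation_test = "sitting")[[session_label]]
}

#' Construct a waveform record
#'
#' A waveform record holds one session's synchronously sampled two-channel
#' recording: an ECG trace and a PPG trace at a common sampling rate.
#' It is a tibble with columns `sample` (0-based index), `t` (seconds, sample
#' `k` is at `k/fs`), `ecg` and `ppg` (arbitrary amplitude units), carrying
#' the sampling rate and session metadata as attributes.
#'
#' @param ecg,ppg Numeric amplitude vectors of equal length (arbitrary units).
#' @param fs Sampling rate in Hz (default 250).
#' @param subject_id,session_label,posture Optional session metadata.
#'   `session_label` must be one of [SESSION_LABELS] when given; `posture`
#'   one of `"sitting"`/`"standing"`.
#' @return A `waveform_record` tibble.
#' @export
waveform_record <- function(ecg, ppg, fs = 250,
                            subject_id = NA_character_,
                            session_label = NA_character_,
                            posture = NA_character_) {
  if (!is.numeric(ecg) || !is.numeric(ppg)) {
    abort_format("`ecg` and `ppg` must be numeric amplitude vectors.")
  }
  if (length(ecg) != length(ppg)) {
    abort_format(sprintf("channel lengths differ: ecg has %d samples, ppg has %d.",
                         length(ecg), length(ppg)))
  }
  if (anyNA(ecg) || anyNA(ppg)) {
    abort_format("missing or NaN samples are not allowed in a waveform record.")
  }
  if (!is_scalar_number(fs) || fs <= 0) abort_param("`fs` must be a positive sampling rate in Hz.")
  if (!is.na(session_label) && !session_label %in% SESSION_LABELS) {
    abort_config(sprintf("unknown session_label '%s' (expected one of %s).",
                         session_label, paste(SESSION_LABELS, collapse = ", ")))
  }
  if (!is.na(posture) && !posture %in% c("sitting", "standing")) {
    abort_config(sprintf("unknown posture '%s'.", posture))
  }
  if (length(ecg) < 2 * fs) {
    warn_validation(sprintf(
      "waveform record is shorter than 2 s (%d samples at %g Hz).", length(ecg), fs))
  }
  k <- seq_along(ecg) - 1L
  out <- tibble(sample = k, t = k / fs, ecg = as.numeric(ecg), ppg = as.numeric(ppg))
  structure(out,
            class = c("waveform_record", class(out)),
            fs = fs, subject_id = subject_id,
            session_label = session_label, posture = posture)
}

#' Sampling rate of a waveform record
#' @param record A [waveform_record()].
#' @return Sampling rate in Hz.
#' @export
record_fs <- function(record) attr(record, "fs")

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf("<waveform_record> %d samples at %g Hz (%.1f s)",
              nrow(x), attr(x, "fs"), nrow(x) / attr(x, "fs")))
  meta <- c(subject = attr(x, "subject_id"), session = attr(x, "session_label"),
            posture = attr(x, "posture"))
  meta <- meta[!is.na(meta)]
  if (length(meta)) cat(" |", paste(names(meta), meta, sep = ": ", collapse = ", "))
  cat("\n")
  NextMethod()
}

#' Read a waveform session from delimited text
#'
#' The on-disk dialect is comma-delimited text with one header row and columns
#' `ecg` and `ppg`; a leading `t` or `sample` column is accepted and ignored
#' for the signal content.
#'
#' @param path Path to a CSV waveform file.
#' @param fs Sampling rate in Hz the file was recorded at (default 250; the
#'   dialect stores samples, not timestamps, so the rate is supplied here).
#' @inheritParams waveform_record
#' @return A [waveform_record()].
#' @export
read_waveform <- function(path, fs = 250,
                          subject_id = NA_character_,
                          session_label = NA_character_,
                          posture = NA_character_) {
  if (!file.exists(path)) abort_format(sprintf("waveform file not found: %s", path))
  dat <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = readr::col_character())),
    error = function(e) abort_format(sprintf("failed to parse waveform file %s: %s",
                                             path, conditionMessage(e))))
  if (nrow(readr::problems(dat)) > 0) {
    abort_format(sprintf("malformed rows in waveform file %s.", path))
  }
  if (!all(c("ecg", "ppg") %in% names(dat))) {
    abort_format(sprintf(
      "waveform file %s must have header columns 'ecg' and 'ppg' (found: %s).",
      path, paste(names(dat), collapse = ", ")))
  }
  # numeric conversion via base strtod: correctly rounded, so 17-digit files
  # round-trip doubles exactly
  num <- function(v) {
    out <- suppressWarnings(as.numeric(v))
    if (any(is.na(out) & !v %in% c("NA", "NaN", ""))) {
      abort_format(sprintf("non-numeric sample values in waveform file %s.", path))
    }
    out
  }
  waveform_record(num(dat$ecg), num(dat$ppg), fs = fs, subject_id = subject_id,
                  session_label = session_label, posture = posture)
}

#' Write a waveform record to delimited text
#'
#' Writes columns `t`, `ecg`, `ppg` with full double precision so that
#' `read_waveform()` reproduces the sample values exactly; repeated writes of
#' the same record are byte-identical.
#'
#' @param record A [waveform_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(record, path) {
  stopifnot(inherits(record, "waveform_record"))
  # 17 significant digits guarantee a lossless double round trip
  dat <- tibble(t = sprintf("%.17g", record$t),
                ecg = sprintf("%.17g", record$ecg),
                ppg = sprintf("%.17g", record$ppg))
  readr::write_csv(dat, path, progress = FALSE, quote = "none")
  invisible(path)
}

#' Load an experiment configuration
#'
#' The experiment config is a JSON document keyed by subject then session,
#' mirroring the protocol outline: each subject lists up to three sessions
#' (see [SESSION_LABELS]) with a waveform file and the ordered oscillometric
#' reference measurements taken in that session.
#'
#' @param path Path to the JSON experiment config.
#' @return A tibble with one row per session descriptor, in config order:
#'   `subject_id`, `session_label`, `posture`, `waveform_path` (resolved
#'   relative to the config file), `fs`, `measurements` (list column of
#'   tibbles with `order_index`, `sbp`, `dbp`) and `subject_complete`
#'   (whether the subject has all three sessions; subjects missing either
#'   calibration posture are flagged incomplete).
#' @export
load_experiment_config <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("experiment config not found: %s", path))
  cfg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(cfg$subjects)) abort_config("experiment config has no 'subjects' entry.")
  fs <- cfg$fs %||% 250
  base <- dirname(normalizePath(path))
  rows <- purrr::map(cfg$subjects, function(subj) {
    sid <- subj$subject_id %||% abort_config("subject without 'subject_id' in config.")
    labels <- purrr::map_chr(subj$sessions, ~ .x$session_label %||% NA_character_)
    bad <- setdiff(labels, SESSION_LABELS)
    if (length(bad)) {
      abort_config(sprintf("unknown session_label '%s' for subject %s.", bad[[1]], sid))
    }
    if (anyDuplicated(labels)) {
      abort_config(sprintf("duplicate session '%s' for subject %s.",
                           labels[duplicated(labels)][[1]], sid))
    }
    complete <- all(SESSION_LABELS %in% labels)
    purrr::map(subj$sessions, function(ss) {
      meas <- purrr::map_dfr(ss$measurements %||% list(), function(m) {
        tibble(order_index = as.integer(m$order_index %||% m$order %||% NA_integer_),
               sbp = as.numeric(m$sbp), dbp = as.numeric(m$dbp))
      })
      wf <- ss$waveform %||% NA_character_
      if (!is.na(wf) && !grepl("^(/|[A-Za-z]:)", wf)) wf <- file.path(base, wf)
      tibble(subject_id = sid,
             session_label = ss$session_label,
             posture = ss$posture %||% default_posture(ss$session_label),
             waveform_path = wf,
             fs = as.numeric(ss$fs %||% fs),
             measurements = list(meas),
             subject_complete = complete)
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}

#' Write an experiment configuration
#'
#' Inverse of [load_experiment_config()]; used by the synthetic cohort
#' generator and available for assembling configs for recorded data.
#'
#' @param sessions A tibble shaped like the output of
#'   [load_experiment_config()] (waveform paths are written as given).
#' @param path Output JSON path.
#' @param fs Cohort-level sampling rate recorded in the config header.
#' @return `path`, invisibly.
#' @export
write_experiment_config <- function(sessions, path, fs = 250) {
  subjects <- sessions |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_map(function(df, key) {
      list(subject_id = key$subject_id,
           sessions = purrr::pmap(
             list(df$session_label, df$posture, df$waveform_path, df$measurements),
             function(label, posture, wf, meas) {
               list(session_label = label, posture = posture, waveform = wf,
                    measurements = purrr::pmap(
                      list(meas$order_index, meas$sbp, meas$dbp),
                      function(oi, s, d) list(order_index = oi, sbp = s, dbp = d)))
             }))
    })
  jsonlite::write_json(list(fs = fs, schema_version = 1L, subjects = subjects),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
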