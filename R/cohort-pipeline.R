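#' Pipeline run configuration
#'
#' Collects the tunable parameters of the estimation pipeline with the
#' protocol defaults: 5-beat feature windows, a 10 ms smoothing window and
#' 250 Hz sampling.
#'
#' @param W Number of past PTT measurements per feature window.
#' @param filter_window_ms Sliding-window filter duration (ms).
#' @param fs_hz Default sampling rate (Hz).
#' @param pttv_convention `"window_differences"` (a window of `W` PTT
#'   values yields `W - 1` successive differences; default) or
#'   `"n_differences"` (`W` differences taken from `W + 1` values).
#' @param fluctuation_cv_threshold,max_unmatched_frac,min_beats
#'   Signal-validity rule, see [check_signal_fluctuation()].
#' @param population_fit_scope `"leave_one_out"` (default: each subject's
#'   compensation constants come from a fit excluding that subject) or
#'   `"pooled"` (all collected data, including the subject's own).
#' @param min_ptt_separation_ms Degenerate-calibration tolerance, see
#'   [calibrate_subject()].
#' @param seed Optional seed recorded with the run.
#' @return A `run_config` list with the derived `pttv_window`.
#' @export
run_config <- function(W = 5, filter_window_ms = 10, fs_hz = 250,
                       pttv_convention = c("window_differences", "n_differences"),
                       fluctuation_cv_threshold = 0.2, max_unmatched_frac = 0.2,
                       min_beats = 10,
                       population_fit_scope = c("leave_one_out", "pooled"),
                       min_ptt_separation_ms = 2, seed = NULL) {
  pttv_convention <- match.arg(pttv_convention)
  population_fit_scope <- match.arg(population_fit_scope)
  if (W < 2 || filter_window_ms <= 0 || fs_hz <= 0 || fluctuation_cv_threshold <= 0) {
    abort_param("run_config thresholds must be positive (and W >= 2).")
  }
  structure(list(W = W,
                 pttv_window = if (pttv_convention == "window_differences") W else W + 1L,
                 pttv_convention = pttv_convention,
                 filter_window_ms = filter_window_ms, fs_hz = fs_hz,
                 fluctuation_cv_threshold = fluctuation_cv_threshold,
                 max_unmatched_frac = max_unmatched_frac, min_beats = min_beats,
                 population_fit_scope = population_fit_scope,
                 min_ptt_separation_ms = min_ptt_separation_ms, seed = seed),
            class = "run_config")
}

analyze_session_record <- function(record, rc) {
  ann <- detect_beats(record, smooth_ms = rc$filter_window_ms)
  ptt <- compute_ptt_series(ann)
  validity <- check_signal_fluctuation(ptt,
                                       cv_threshold = rc$fluctuation_cv_threshold,
                                       max_unmatched_frac = rc$max_unmatched_frac,
                                       min_beats = rc$min_beats)
  list(ptt = ptt, annotations = ann, validity = validity)
}

cohort_session_list <- function(x) {
  if (inherits(x, "ptt_cohort")) {
    purrr::map_dfr(x$subjects, function(subj) {
      purrr::map_dfr(subj$sessions, function(ss) {
        tibble(subject_id = subj$subject_id, session_label = ss$session_label,
               posture = ss$posture, record = list(ss$record),
               measurements = list(ss$measurements))
      })
    })
  } else {
    cfg <- if (is.character(x)) load_experiment_config(x) else x
    cfg |>
      dplyr::mutate(record = purrr::pmap(
        list(.data$waveform_path, .data$fs, .data$subject_id,
             .data$session_label, .data$posture),
        function(path, fs, sid, label, posture) {
          read_waveform(path, fs = fs, subject_id = sid,
                        session_label = label, posture = posture)
        })) |>
      dplyr::select("subject_id", "session_label", "posture", "record", "measurements")
  }
}

#' Run beat detection, PTT extraction and validity checks over a cohort
#'
#' Accepts an in-memory cohort from [simulate_cohort()], a path to an
#' experiment config JSON, or a loaded config tibble; every session is
#' processed through smoothing, R-peak and pulse detection, PTT
#' computation, the fluctuation validity check and the reference-pressure
#' resolution rules.
#'
#' @param x A `ptt_cohort`, a config path, or a [load_experiment_config()]
#'   tibble.
#' @param rc A [run_config()].
#' @return A `cohort_analysis` tibble, one row per session: identifiers,
#'   beat counts, `valid_signal`, `bp_status`, `resolved_sbp`/`_dbp`,
#'   `valid` (signal valid and pressure accepted) and list columns `ptt`
#'   and `validity`.
#' @export
analyze_cohort <- function(x, rc = run_config()) {
  sessions <- cohort_session_list(x)
  out <- sessions |>
    dplyr::mutate(processed = purrr::map(.data$record, analyze_session_record, rc = rc),
                  ptt = purrr::map(.data$processed, "ptt"),
                  validity = purrr::map(.data$processed, "validity"),
                  n_beats = purrr::map_int(.data$ptt, nrow),
                  valid_signal = purrr::map_lgl(.data$validity, "valid"),
                  resolution = purrr::map(.data$measurements, resolve_reference_bp),
                  bp_status = purrr::map_chr(.data$resolution, "status"),
                  resolved_sbp = purrr::map_dbl(.data$resolution, "resolved_sbp"),
                  resolved_dbp = purrr::map_dbl(.data$resolution, "resolved_dbp"),
                  valid = .data$valid_signal & startsWith(.data$bp_status, "accepted")) |>
    dplyr::select("subject_id", "session_label", "posture", "n_beats",
                  "valid_signal", "bp_status", "resolved_sbp", "resolved_dbp",
                  "valid", "ptt", "validity")
  structure(out, rc = rc, class = c("cohort_analysis", class(out)))
}

session_row <- function(analysis, sid, label) {
  row <- dplyr::filter(analysis, .data$subject_id == sid, .data$session_label == label)
  if (nrow(row) != 1) abort_param(sprintf("no unique %s session for subject %s.", label, sid))
  row
}

#' Fit population constants and personalise every analyzable subject
#'
#' Implements the two-stage calibration: (1) the population regression of
#' resolved reference pressure on the pooled session-level features (one
#' data point per subject-session, since the cuff yields one reference per
#' session) to obtain the compensation constants `c` and `d`; (2) the
#' per-subject two-posture solve of `a` and `b` with `c`, `d` fixed. The
#' linear baseline model is calibrated from the same two postures with
#' `c = d = 0`. With scope `"leave_one_out"` each subject's `c`, `d` come
#' from a fit excluding that subject's sessions.
#'
#' @param analysis A [analyze_cohort()] result.
#' @param rc A [run_config()].
#' @return A `cohort_calibration` list: `profiles` (named list of
#'   [calibration_profile()]s), `population` (pooled `bp_population_fit`
#'   per pressure type), `rows` (the pooled regression table), `excluded`
#'   (tibble of skipped subjects with reasons) and `summary`
#'   ([validate_experiment()]).
#' @export
calibrate_cohort <- function(analysis, rc = attr(analysis, "rc") %||% run_config()) {
  summary <- validate_experiment(analysis)
  ok_ids <- summary$subjects$subject_id[summary$subjects$analyzable]
  excluded <- summary$subjects |>
    dplyr::filter(!.data$analyzable) |>
    dplyr::transmute(.data$subject_id,
                     reason = ifelse(nzchar(.data$failed_sessions),
                                     paste("invalid sessions:", .data$failed_sessions),
                                     "incomplete session set"))
  if (!length(ok_ids)) abort_param("no analyzable subjects to calibrate.")
  per_subject <- purrr::map(ok_ids, function(sid) {
    sit <- session_row(analysis, sid, "calibration_sitting")
    reference <- session_reference(sit$ptt[[1]], W = rc$W, pttv_window = rc$pttv_window)
    summaries <- purrr::map(SESSION_LABELS, function(label) {
      row <- session_row(analysis, sid, label)
      dplyr::bind_cols(
        tibble(subject_id = sid, session_label = label),
        session_summary(row$ptt[[1]], reference, W = rc$W, pttv_window = rc$pttv_window),
        tibble(resolved_sbp = row$resolved_sbp, resolved_dbp = row$resolved_dbp))
    }) |> dplyr::bind_rows()
    list(subject_id = sid, reference = reference, summaries = summaries)
  })
  names(per_subject) <- ok_ids
  rows <- purrr::map_dfr(per_subject, function(ps) {
    dplyr::mutate(ps$summaries, dpttv_ms = .data$pttv_ms - ps$reference$pttv0_ms)
  })
  fit_type <- function(data, type) {
    resp <- if (type == "SBP") data$resolved_sbp else data$resolved_dbp
    fit_population_coefficients(dplyr::mutate(data, bp_mmHg = resp), type)
  }
  population <- list(SBP = fit_type(rows, "SBP"), DBP = fit_type(rows, "DBP"))
  profiles <- list()
  for (sid in ok_ids) {
    ps <- per_subject[[sid]]
    pop <- if (rc$population_fit_scope == "leave_one_out" && length(ok_ids) > 1) {
      loo <- dplyr::filter(rows, .data$subject_id != sid)
      list(SBP = fit_type(loo, "SBP"), DBP = fit_type(loo, "DBP"))
    } else {
      population
    }
    point <- function(label, type) {
      s <- dplyr::filter(ps$summaries, .data$session_label == label)
      tibble(mean_ptt_ms = s$mean_ptt_ms, pttv_ms = s$pttv_ms, vptt = s$vptt,
             bp_mmHg = if (type == "SBP") s$resolved_sbp else s$resolved_dbp)
    }
    prof <- tryCatch({
      coeff_rows <- purrr::map_dfr(c("SBP", "DBP"), function(type) {
        comp <- calibrate_subject(point("calibration_sitting", type),
                                  point("calibration_standing", type),
                                  pop[[type]]$coefficients, ps$reference,
                                  min_ptt_separation_ms = rc$min_ptt_separation_ms)
        lin_pop <- coefficient_set(0, 0, c = 0, d = 0, pressure_type = type)
        lin <- calibrate_subject(point("calibration_sitting", type),
                                 point("calibration_standing", type),
                                 lin_pop, ps$reference,
                                 min_ptt_separation_ms = rc$min_ptt_separation_ms)
        dplyr::bind_rows(dplyr::mutate(comp, model = "compensated"),
                         dplyr::mutate(lin, model = "linear"))
      })
      calibration_profile(sid, ps$reference, coeff_rows)
    }, pttbp_degenerate_calibration = function(e) {
      warn_validation(sprintf("subject %s skipped: %s", sid, conditionMessage(e)))
      excluded <<- dplyr::bind_rows(excluded,
                                    tibble(subject_id = sid, reason = conditionMessage(e)))
      NULL
    })
    if (!is.null(prof)) profiles[[sid]] <- prof
  }
  structure(list(profiles = profiles, population = population, rows = rows,
                 excluded = excluded, summary = summary, rc = rc),
            class = "cohort_calibration")
}

#' @export
print.cohort_calibration <- function(x, ...) {
  cat(sprintf("<cohort_calibration> %d profiles (%s population fit on %d points)\n",
              length(x$profiles), x$rc$population_fit_scope, nrow(x$rows)))
  invisible(x)
}

#' Per-beat blood pressure estimates over the estimation-test sessions
#'
#' @param analysis A [analyze_cohort()] result.
#' @param calibration A [calibrate_cohort()] result (or a named list of
#'   profiles).
#' @param model `"compensated"`, `"linear"` or `"both"`.
#' @param rc A [run_config()].
#' @return Tibble of per-beat estimates with `subject_id`, `beat`,
#'   `beat_time_s`, `model`, `sbp_mmHg`, `dbp_mmHg`.
#' @export
estimate_cohort <- function(analysis, calibration,
                            model = c("both", "compensated", "linear"),
                            rc = attr(analysis, "rc") %||% run_config()) {
  model <- match.arg(model)
  models <- if (model == "both") c("compensated", "linear") else model
  profiles <- if (inherits(calibration, "cohort_calibration")) {
    calibration$profiles
  } else {
    calibration
  }
  purrr::map_dfr(names(profiles), function(sid) {
    row <- session_row(analysis, sid, "estimation_test")
    session <- list(ptt = row$ptt[[1]], validity = row$validity[[1]])
    purrr::map_dfr(models, function(m) {
      dplyr::mutate(estimate_session(session, profiles[[sid]], model = m, rc = rc),
                    subject_id = sid, .before = 1)
    })
  })
}

#' Run the full experiment on a cohort
#'
#' Convenience wrapper chaining [analyze_cohort()], [calibrate_cohort()],
#' [estimate_cohort()] (both models) and [evaluate_cohort()].
#'
#' @param cohort A `ptt_cohort`, config path or config tibble.
#' @param rc A [run_config()].
#' @param model Passed to [estimate_cohort()].
#' @return A `bp_experiment` list: `analysis`, `calibration`, `estimates`,
#'   `agreement`, `summary`.
#' @export
run_experiment <- function(cohort, rc = run_config(), model = "both") {
  analysis <- analyze_cohort(cohort, rc)
  calibration <- calibrate_cohort(analysis, rc)
  estimates <- estimate_cohort(analysis, calibration, model = model, rc = rc)
  agreement <- evaluate_cohort(estimates, analysis)
  structure(list(analysis = analysis, calibration = calibration,
                 estimates = estimates, agreement = agreement,
                 summary = calibration$summary, rc = rc),
            class = "bp_experiment")
}

#' @export
print.bp_experiment <- function(x, ...) {
  print(x$summary)
  print(as_tibble(x$agreement))
  invisible(x)
}

#' @rdname run_experiment
#' @param x A `bp_experiment`.
#' @param ... Unused.
#' @export
tidy.bp_experiment <- function(x, ...) as_tibble(x$agreement)

#' @rdname run_experiment
#' @export
glance.bp_experiment <- function(x, ...) {
  tibble(n_subjects = x$summary$n_subjects,
         n_analyzable = x$summary$n_analyzable,
         n_datasets = x$summary$n_datasets,
         n_profiles = length(x$calibration$profiles))
}
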