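#' Resolve one pressure type's repeated oscillometric measurements
#'
#' The routine data-collection procedure measures cuff blood pressure twice
#' per session (with an optional third measurement) and accepts the session
#' only when the repeats agree: if the first two measurements differ by less
#' than 5 mmHg the first is adopted; if the difference lies between 5 and
#' 10 mmHg (inclusive on both ends, the only reading that partitions the
#' line) a third measurement after rest is required and the mean of the
#' three is adopted; if it exceeds 10 mmHg the session is discarded as
#' unstable. The rule is positional: the "first" measurement is the first
#' in session order.
#'
#' @param values Numeric vector of 2 or 3 measurements (mmHg) in session
#'   order, for one pressure type.
#' @return One-row tibble: `status` (one of `accepted_first`,
#'   `accepted_mean_of_three`, `pending_third`, `discarded`), `resolved`
#'   (mmHg, `NA` unless accepted), `diff` (|m1 - m2|), `reason`.
#' @export
resolve_measurement_series <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) abort_param("at least 2 measurements are required.")
  if (length(values) > 3) abort_param("more than 3 measurements are not part of the protocol.")
  if (anyNA(values)) abort_param("measurements must not be missing.")
  d <- abs(values[1] - values[2])
  if (d < 5) {
    status <- "accepted_first"; resolved <- values[1]
    reason <- sprintf("first two measurements differ by %.1f mmHg (< 5)", d)
  } else if (d <= 10) {
    if (length(values) == 3) {
      status <- "accepted_mean_of_three"; resolved <- mean(values)
      reason <- sprintf("difference %.1f mmHg in [5, 10]; mean of three adopted", d)
    } else {
      status <- "pending_third"; resolved <- NA_real_
      reason <- sprintf("difference %.1f mmHg in [5, 10]; third measurement required", d)
    }
  } else {
    status <- "discarded"; resolved <- NA_real_
    reason <- sprintf("difference %.1f mmHg exceeds 10; session data discarded", d)
  }
  tibble(status = status, resolved = resolved, diff = d, reason = reason)
}

#' Resolve a session's reference blood pressure
#'
#' Applies [resolve_measurement_series()] independently to the systolic and
#' diastolic series of a session's measurements. The joint session status is
#' conservative: the session is discarded if either pressure type is
#' discarded, pending if either still needs a third measurement, and
#' accepted otherwise (each type resolving by its own rule).
#'
#' @param measurements Tibble with columns `order_index`, `sbp`, `dbp`
#'   (2 or 3 rows in session order).
#' @return One-row tibble: `status` (joint), `resolved_sbp`, `resolved_dbp`,
#'   `sbp_status`, `dbp_status`, `reason`. Resolved values are present iff
#'   the joint status is accepted.
#' @export
resolve_reference_bp <- function(measurements) {
  if (!is.data.frame(measurements) || !all(c("sbp", "dbp") %in% names(measurements))) {
    abort_param("`measurements` must be a tibble with columns sbp and dbp.")
  }
  if ("order_index" %in% names(measurements)) {
    measurements <- dplyr::arrange(measurements, .data$order_index)
  }
  bad <- measurements$dbp < 40 | measurements$dbp >= measurements$sbp | measurements$sbp > 300
  if (any(bad)) {
    abort_param("implausible measurement (need 40 <= dbp < sbp <= 300 mmHg).")
  }
  rs <- resolve_measurement_series(measurements$sbp)
  rd <- resolve_measurement_series(measurements$dbp)
  status <- if (rs$status == "discarded" || rd$status == "discarded") {
    "discarded"
  } else if (rs$status == "pending_third" || rd$status == "pending_third") {
    "pending_third"
  } else if (rs$status == "accepted_first" && rd$status == "accepted_first") {
    "accepted_first"
  } else {
    "accepted_mean_of_three"
  }
  accepted <- startsWith(status, "accepted")
  tibble(status = status,
         resolved_sbp = if (accepted) rs$resolved else NA_real_,
         resolved_dbp = if (accepted) rd$resolved else NA_real_,
         sbp_status = rs$status, dbp_status = rd$status,
         reason = paste0("SBP: ", rs$reason, "; DBP: ", rd$reason))
}

#' Summarise cohort validity
#'
#' A subject is analyzable iff all three protocol sessions are present and
#' valid: the waveform fluctuation check passed and the reference blood
#' pressure resolved to an accepted value.
#'
#' @param analysis A `cohort_analysis` tibble from [analyze_cohort()] (or
#'   any tibble with columns `subject_id`, `session_label`, `valid`).
#' @return A `cohort_summary` list: `subjects` (per-subject tibble with
#'   `analyzable` and failure reasons), `n_subjects`, `n_analyzable`,
#'   `n_datasets` (sessions contributed by analyzable subjects).
#' @export
validate_experiment <- function(analysis) {
  need <- c("subject_id", "session_label", "valid")
  if (!all(need %in% names(analysis))) {
    abort_param(sprintf("`analysis` must have columns %s.", paste(need, collapse = ", ")))
  }
  subjects <- analysis |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      n_sessions = dplyr::n(),
      complete = all(SESSION_LABELS %in% .data$session_label),
      n_valid = sum(.data$valid),
      analyzable = .data$complete & all(.data$valid),
      failed_sessions = paste(.data$session_label[!.data$valid], collapse = ", "),
      .groups = "drop")
  structure(list(subjects = subjects,
                 n_subjects = nrow(subjects),
                 n_analyzable = sum(subjects$analyzable),
                 n_datasets = 3L * sum(subjects$analyzable)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d/%d subjects analyzable (%d datasets)\n",
              x$n_analyzable, x$n_subjects, x$n_datasets))
  excl <- dplyr::filter(x$subjects, !.data$analyzable)
  if (nrow(excl)) {
    cat("excluded:\n")
    for (i in seq_len(nrow(excl))) {
      cat(sprintf("  %s (%s)\n", excl$subject_id[i],
                  if (nzchar(excl$failed_sessions[i])) excl$failed_sessions[i] else "incomplete"))
    }
  }
  invisible(x)
}
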