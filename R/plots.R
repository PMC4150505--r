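#' Bland-Altman plot of a cohort agreement report
#'
#' @param object A `bp_agreement` from [evaluate_cohort()].
#' @param type `"bland_altman"` (difference vs mean, with the bias and
#'   limits of agreement) or `"scatter"` (estimate vs reference with the
#'   identity and least-squares lines).
#' @param ... Unused.
#' @return A ggplot object faceted by model and pressure type.
#' @export
autoplot.bp_agreement <- function(object, type = c("bland_altman", "scatter"), ...) {
  type <- match.arg(type)
  paired <- attr(object, "paired")
  if (is.null(paired)) abort_param("agreement report carries no paired data to plot.")
  if (type == "bland_altman") {
    dat <- dplyr::mutate(paired,
                         avg = (.data$estimate + .data$reference) / 2,
                         diff = .data$estimate - .data$reference)
    lines <- as_tibble(object) |>
      tidyr::pivot_longer(c("mean_error_mmHg", "loa_low_mmHg", "loa_high_mmHg"),
                          names_to = "which", values_to = "y") |>
      dplyr::mutate(linetype = ifelse(.data$which == "mean_error_mmHg",
                                      "bias", "limit of agreement"))
    ggplot2::ggplot(dat, ggplot2::aes(x = .data$avg, y = .data$diff)) +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::geom_hline(data = lines,
                          ggplot2::aes(yintercept = .data$y, linetype = .data$linetype),
                          colour = "steelblue") +
      ggplot2::facet_grid(pressure_type ~ model, scales = "free") +
      ggplot2::labs(x = "Mean of estimate and reference (mmHg)",
                    y = "Estimate - reference (mmHg)", linetype = NULL) +
      ggplot2::theme_bw()
  } else {
    ggplot2::ggplot(paired, ggplot2::aes(x = .data$reference, y = .data$estimate)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                           colour = "steelblue", linewidth = 0.6) +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::facet_grid(pressure_type ~ model, scales = "free") +
      ggplot2::labs(x = "Reference blood pressure (mmHg)",
                    y = "Estimated blood pressure (mmHg)") +
      ggplot2::theme_bw()
  }
}

#' Quick waveform segment plot with detected fiducials
#'
#' @param record A [waveform_record()].
#' @param annotations Optional `beat_annotations` to overlay.
#' @param from_s,to_s Time window to display (defaults to the first 10 s).
#' @return A ggplot object.
#' @export
plot_waveforms <- function(record, annotations = NULL, from_s = 0, to_s = 10) {
  stopifnot(inherits(record, "waveform_record"))
  dat <- record |>
    dplyr::filter(.data$t >= from_s, .data$t <= to_s) |>
    tidyr::pivot_longer(c("ecg", "ppg"), names_to = "channel", values_to = "amplitude")
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$t, y = .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = "Amplitude (a.u.)") +
    ggplot2::theme_bw()
  if (!is.null(annotations)) {
    fs <- record_fs(record)
    marks <- dplyr::bind_rows(
      tibble(t = (annotations$r_peaks - 1) / fs, channel = "ecg"),
      tibble(t = (annotations$pairs$ppg_index - 1) / fs, channel = "ppg")) |>
      dplyr::filter(.data$t >= from_s, .data$t <= to_s)
    p <- p + ggplot2::geom_vline(data = marks, ggplot2::aes(xintercept = .data$t),
                                 colour = "firebrick", alpha = 0.4, linewidth = 0.2)
  }
  p
}
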