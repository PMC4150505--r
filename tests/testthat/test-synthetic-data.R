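flat_law <- function(...) {
  subject_law(coeffs = tibble::tibble(pressure_type = c("SBP", "DBP"),
                                      a = c(-0.45, -0.15), b = c(206, 103),
                                      c = c(-40, -60), d = c(0.8, 3.5)),
              subject_id = "T", ...)
}

test_that("a dynamics-free law yields constant PTT and constant BP", {
  law <- flat_law(lf_variability_amp_ms = 0, ptt_jitter_sd_ms = 0, hr_jitter_cv = 0)
  truth <- generate_beat_sequence(law, "sitting", 40, seed = 1)
  expect_equal(length(unique(truth$ptt_ms)), 1)
  bp <- truth$true_sbp_mmHg[!is.na(truth$true_sbp_mmHg)]
  expect_equal(length(unique(bp)), 1)
  # and the constant follows the law: vptt = 0, pttv = pttv0 = 0
  cf <- dplyr::filter(law$coeffs, pressure_type == "SBP")
  expect_equal(unique(bp), cf$a * unique(truth$ptt_ms) + cf$b)
})

test_that("postures differ in mean PTT by exactly the programmed shift", {
  law <- flat_law(lf_variability_amp_ms = 0, ptt_jitter_sd_ms = 0, hr_jitter_cv = 0,
                  posture_ptt_shift_ms = -16)
  sit <- generate_beat_sequence(law, "sitting", 40, seed = 2)
  ref <- attr(sit, "reference")
  sta <- generate_beat_sequence(law, "standing", 40, seed = 2, reference = ref)
  expect_equal(mean(sta$ptt_ms[sta$measurable]) - mean(sit$ptt_ms[sit$measurable]), -16)
})

test_that("identical seeds give identical truth tables and cohorts", {
  law <- flat_law()
  t1 <- generate_beat_sequence(law, "sitting", 40, seed = 42)
  t2 <- generate_beat_sequence(law, "sitting", 40, seed = 42)
  expect_identical(tibble::as_tibble(t1), tibble::as_tibble(t2))
  c1 <- simulate_cohort(2, cohort_config(duration_s = 40), seed = 42)
  c2 <- simulate_cohort(2, cohort_config(duration_s = 40), seed = 42)
  expect_identical(c1$subjects[[2]]$sessions[[3]]$truth$ptt_ms,
                   c2$subjects[[2]]$sessions[[3]]$truth$ptt_ms)
  expect_identical(c1$subjects[[1]]$sessions[[1]]$record$ecg,
                   c2$subjects[[1]]$sessions[[1]]$record$ecg)
  expect_identical(c1$subjects[[1]]$sessions[[1]]$measurements,
                   c2$subjects[[1]]$sessions[[1]]$measurements)
})

test_that("rendered PPG maxima sit exactly at R + PTT on the grid", {
  law <- flat_law(lf_variability_amp_ms = 0, ptt_jitter_sd_ms = 0, hr_jitter_cv = 0,
                  baseline_ptt_ms = 200)
  truth <- generate_beat_sequence(law, "sitting", 40, seed = 3)
  rec <- render_waveforms(truth)
  fs <- 250
  for (i in c(1, 10, 20)) {
    ctr <- truth$r_sample[i] + 1 + round(0.2 * fs)
    win <- rec$ppg[(ctr - 20):(ctr + 20)]
    expect_equal(which.max(win), 21)  # maximum at the programmed sample
  }
  # ECG peak count ~ heart rate: 60 s at 60 bpm -> about 60 beats
  law60 <- flat_law(heart_rate_bpm = 60)
  t60 <- generate_beat_sequence(law60, "sitting", 60, seed = 4)
  expect_gt(nrow(t60), 54)
  expect_lt(nrow(t60), 63)
})

test_that("a PTT exceeding its beat interval is a generation error", {
  law <- flat_law()
  truth <- generate_beat_sequence(law, "sitting", 40, seed = 5)
  bad <- truth
  bad$ptt_ms[3] <- (bad$r_sample[4] - bad$r_sample[3] + 10) * 1000 / 250
  expect_error(render_waveforms(bad), class = "pttbp_generation_error")
})

test_that("generate_cohort writes session files, truth tables and a loadable config", {
  dir <- withr::local_tempdir()
  res <- generate_cohort(2, file.path(dir, "c"), cohort_config(duration_s = 40), seed = 6)
  expect_equal(nrow(res$sessions), 6)
  expect_length(list.files(file.path(dir, "c"), pattern = "^S.*\\.csv$"), 6)
  expect_length(list.files(file.path(dir, "c", "truth")), 6)
  cfg <- load_experiment_config(res$config_path)
  expect_equal(nrow(cfg), 6)
  # refuses to clobber unless told to
  expect_error(generate_cohort(1, file.path(dir, "c"), seed = 6),
               class = "pttbp_config_error")
})

test_that("the full pipeline inverts a noise-free model-consistent cohort", {
  co <- recovery_cohort(3, seed = 17, duration_s = 60)
  rc <- run_config(population_fit_scope = "pooled")
  a <- analyze_cohort(co, rc)
  cal <- calibrate_cohort(a, rc)
  est <- estimate_cohort(a, cal, model = "compensated", rc = rc)
  for (subj in co$subjects) {
    truth <- dplyr::filter(subj$sessions$estimation_test$truth,
                           !is.na(true_sbp_mmHg), measurable)
    mine <- dplyr::filter(est, subject_id == subj$subject_id)
    expect_equal(nrow(mine), nrow(truth))
    expect_lt(max(abs(mine$sbp_mmHg - truth$true_sbp_mmHg)), 1)
    expect_lt(max(abs(mine$dbp_mmHg - truth$true_dbp_mmHg)), 1)
  }
})
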