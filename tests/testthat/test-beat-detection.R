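test_that("sliding-window filter matches the direct neighbourhood-mean oracle", {
  expect_equal(sliding_window_filter(c(5, 5, 5, 5), 250, 10), c(5, 5, 5, 5))
  x <- c(0, 3, 0, 3, 0)
  expect_equal(sliding_window_filter(x, 250, 4), x)  # sub-sample window -> identity
  # 10 ms at 250 Hz rounds to a 3-sample centred window; edges shrink to width 1
  got <- sliding_window_filter(x, 250, 10)
  want <- c(x[1], mean(x[1:3]), mean(x[2:4]), mean(x[3:5]), x[5])
  expect_equal(got, want)
  # length preserved and linear-phase for arbitrary signals
  set.seed(1)
  y <- rnorm(101)
  expect_length(sliding_window_filter(y, 250, 50), 101)
  expect_error(sliding_window_filter(y, 250, 10000), class = "pttbp_parameter_error")
})

test_that("R-peaks are recovered exactly on clean rendered ECG and absent on flat signals", {
  cfg <- config_noise_free(cohort_config(duration_s = 40))
  co <- simulate_cohort(1, cfg, seed = 3)
  ss <- co$subjects[[1]]$sessions$calibration_sitting
  det <- detect_r_peaks(ss$record$ecg, 250)
  truth <- ss$truth$r_sample + 1
  expect_equal(det, truth)  # grid-exact on noise-free morphology
  expect_warning(flat <- detect_r_peaks(rep(0, 5000), 250),
                 class = "pttbp_validation_warning")
  expect_length(flat, 0)
})

test_that("the refractory period suppresses double detections", {
  co <- simulate_cohort(1, config_noise_free(cohort_config(duration_s = 40)), seed = 3)
  det <- detect_r_peaks(co$subjects[[1]]$sessions[[1]]$record$ecg, 250)
  expect_true(all(diff(det) >= round(0.25 * 250)))
})

test_that("noisy ECG at 20 dB SNR still yields near-perfect beat matching", {
  cfg <- config_noise_free(cohort_config(duration_s = 60))
  co <- simulate_cohort(3, cfg, seed = 9)
  fracs <- purrr::map_dbl(co$subjects, function(subj) {
    truth <- subj$sessions$estimation_test$truth
    clean <- render_waveforms(truth)
    noisy <- clean$ecg + rnorm(length(clean$ecg), 0, snr_noise_sd(clean$ecg, 20))
    det <- detect_r_peaks(noisy, 250)
    match_fraction(det, truth$r_sample + 1, tol = 2)
  })
  expect_true(all(fracs >= 0.99))
})

test_that("PPG pulses pair within their cardiac cycle at the programmed offset", {
  fs <- 250
  r <- seq(251, by = 250, length.out = 20)  # 1 Hz beats
  n <- 6000
  ppg <- numeric(n)
  half <- 0.15 * fs
  for (p in r + 50) {  # pulses 200 ms after each R
    j <- max(1, p - floor(half)):min(n, p + floor(half))
    ppg[j] <- ppg[j] + 0.5 * (1 + cos(pi * (j - p) / half))
  }
  ann <- detect_ppg_peaks(ppg, fs, r)
  expect_equal(nrow(ann$pairs), 19)  # last cycle is unbounded
  expect_true(all(ann$pairs$ppg_index - ann$pairs$r_index == 50))
  expect_true(all(ann$pairs$ppg_index > ann$pairs$r_index))
  expect_true(all(ann$pairs$ppg_index < r[-1]))
  # injective pairing
  expect_false(any(duplicated(ann$pairs$r_index)))
  expect_false(any(duplicated(ann$pairs$ppg_index)))
})

test_that("cycles with no acceptable pulse peak stay unmatched", {
  fs <- 250
  r <- c(251, 501, 751)
  ppg <- numeric(1200)
  expect_equal(nrow(detect_ppg_peaks(ppg, fs, r)$pairs), 0)  # identically zero PPG
  # pulse maximum past the 600 ms physiologic bound: that cycle stays unmatched
  r <- c(1, 501)
  p <- 1 + 175  # 700 ms after the first R
  half <- 0.15 * fs
  ppg <- numeric(1200)
  j <- (p - floor(half)):(p + floor(half))
  ppg[j] <- 0.5 * (1 + cos(pi * (j - p) / half))
  ann <- detect_ppg_peaks(ppg, fs, r)
  expect_equal(nrow(ann$pairs), 0)
  expect_warning(detect_ppg_peaks(ppg, fs, r_peaks = 100),
                 class = "pttbp_validation_warning")
})

test_that("PTT series arithmetic and successive differences are exact", {
  ann <- structure(list(r_peaks = c(1L, 251L),
                        ppg_peaks = c(51L),
                        pairs = tibble::tibble(r_index = 1L, ppg_index = 51L),
                        n_cycles = 1L, fs = 250), class = "beat_annotations")
  s <- compute_ptt_series(ann)
  expect_equal(s$ptt_ms, 200)  # 50 samples at 250 Hz
  ann$pairs <- tibble::tibble(r_index = c(1L, 251L), ppg_index = c(51L, 304L))
  s <- compute_ptt_series(ann)
  expect_equal(s$ptt_ms, c(200, 212))
  expect_equal(s$delta_ms, c(NA, 12))
})

test_that("fluctuation validity separates stable, unstable and short series", {
  ok <- check_signal_fluctuation(rep(200, 20))
  expect_true(ok$valid)
  bad <- check_signal_fluctuation(c(rep(100, 10), rep(300, 10)))  # CV = 0.5
  expect_false(bad$valid)
  expect_gt(bad$cv, 0.2)
  short <- check_signal_fluctuation(rep(200, 9))
  expect_false(short$valid)
  expect_match(short$reason, "insufficient beats")
  unmatched <- check_signal_fluctuation(rep(200, 20), n_cycles = 40)
  expect_false(unmatched$valid)
  expect_match(unmatched$reason, "unmatched")
})
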