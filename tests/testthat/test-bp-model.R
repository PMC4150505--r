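fw_row <- function(mean_ptt, pttv = 0, vptt = 0) {
  tibble::tibble(mean_ptt_ms = mean_ptt, pttv_ms = pttv, vptt = vptt)
}

test_that("the compensated estimate reproduces hand-computed values", {
  ref <- tibble::tibble(ptt0_ms = 200, pttv0_ms = 1)
  cs <- coefficient_set(-0.5, 220, 0, 0, "SBP")
  expect_equal(estimate_bp(fw_row(200), cs, ref)$bp_mmHg, 120)
  cs2 <- coefficient_set(-0.5, 220, -40, 2, "SBP")
  # mean PTT 210 -> vptt 0.05; pttv 1 equals pttv0 -> only the c term acts
  expect_equal(estimate_bp(fw_row(210, pttv = 1, vptt = 0.05), cs2, ref)$bp_mmHg,
               115 - 2)
})

test_that("the linear baseline is a*PTT + b on the windowed mean", {
  expect_equal(estimate_bp_linear(fw_row(987), 0, 120)$bp_mmHg, 120)
  expect_equal(estimate_bp_linear(fw_row(200), -0.5, 220)$bp_mmHg, 120)
  expect_equal(estimate_bp_linear(fw_row(180), -0.5, 220)$bp_mmHg, 130)
})

test_that("c = d = 0 reduces the compensated model to the linear baseline exactly", {
  set.seed(21)
  ref <- tibble::tibble(ptt0_ms = 205, pttv0_ms = 2)
  fw <- tibble::tibble(mean_ptt_ms = 200 + rnorm(50, sd = 8),
                       pttv_ms = abs(rnorm(50)), vptt = rnorm(50, sd = 0.05))
  cs <- coefficient_set(-0.4, 215, 0, 0, "SBP")
  expect_identical(estimate_bp(fw, cs, ref)$bp_mmHg,
                   estimate_bp_linear(fw, -0.4, 215)$bp_mmHg)
})

test_that("estimates are strictly decreasing in PTT for a negative slope", {
  ref <- tibble::tibble(ptt0_ms = 200, pttv0_ms = 0)
  cs <- coefficient_set(-0.3, 180, -20, 1, "SBP")
  fw <- tibble::tibble(mean_ptt_ms = seq(160, 260, by = 5), pttv_ms = 1, vptt = 0.02)
  expect_true(all(diff(estimate_bp(fw, cs, ref)$bp_mmHg) < 0))
})

test_that("the population fit recovers exact coefficients and flags degeneracy", {
  set.seed(31)
  truth <- list(a = -0.4, b = 210, c = -35, d = 2.5)
  dat <- tibble::tibble(mean_ptt_ms = 200 + rnorm(40, sd = 20),
                        vptt = rnorm(40, sd = 0.05),
                        dpttv_ms = rnorm(40, sd = 1.5))
  dat$bp_mmHg <- truth$a * dat$mean_ptt_ms + truth$b + truth$c * dat$vptt +
    truth$d * dat$dpttv_ms
  fit <- fit_population_coefficients(dat, "SBP")
  cf <- fit$coefficients
  expect_equal(c(cf$a, cf$b, cf$c, cf$d), unlist(truth, use.names = FALSE),
               tolerance = 1e-9)
  td <- suppressWarnings(tidy(fit))  # summary.lm warns on an exact fit
  expect_equal(td$term, c("a", "b", "c", "d"))
  expect_equal(td$estimate[td$term == "c"], truth$c, tolerance = 1e-6)
  expect_equal(suppressWarnings(glance(fit))$nobs, 40)
  # all compensation columns zero -> no information for c and d
  degen <- dplyr::mutate(dat, vptt = 0, dpttv_ms = 0)
  expect_error(fit_population_coefficients(degen, "SBP"),
               class = "pttbp_parameter_error", regexp = "vptt")
})

test_that("two-posture calibration solves the 2x2 system in closed form", {
  ref <- tibble::tibble(ptt0_ms = 210, pttv0_ms = 1)
  sitting <- tibble::tibble(mean_ptt_ms = 210, pttv_ms = 1, vptt = 0, bp_mmHg = 118)
  standing <- tibble::tibble(mean_ptt_ms = 195, pttv_ms = 1, vptt = (195 - 210) / 210,
                             bp_mmHg = 126)
  pop0 <- coefficient_set(0, 0, 0, 0, "SBP")
  cf <- calibrate_subject(sitting, standing, pop0, ref)
  expect_equal(cf$a, (126 - 118) / (195 - 210))
  expect_equal(cf$b, 118 - cf$a * 210)
  expect_equal(cf$b, 230)
  # identical posture PTT -> ill-conditioned system
  expect_error(calibrate_subject(sitting, dplyr::mutate(standing, mean_ptt_ms = 210.5),
                                 pop0, ref),
               class = "pttbp_degenerate_calibration")
})

test_that("calibration inverts data generated from a known law with fixed c, d", {
  ref <- tibble::tibble(ptt0_ms = 205, pttv0_ms = 1.2)
  pop <- coefficient_set(0, 0, -30, 2, "SBP")
  truth <- list(a = -0.52, b = 224)
  mk <- function(ptt, pttv) {
    vptt <- (ptt - 205) / 205
    tibble::tibble(mean_ptt_ms = ptt, pttv_ms = pttv, vptt = vptt,
                   bp_mmHg = truth$a * ptt + truth$b + pop$c * vptt +
                     pop$d * (pttv - 1.2))
  }
  cf <- calibrate_subject(mk(205, 1.2), mk(188, 2.1), pop, ref)
  expect_equal(cf$a, truth$a, tolerance = 1e-12)
  expect_equal(cf$b, truth$b, tolerance = 1e-12)
})

test_that("profiles serialise to JSON and back without loss", {
  ref <- tibble::tibble(ptt0_ms = 207.25, pttv0_ms = 1.125)
  coeffs <- dplyr::bind_rows(
    dplyr::mutate(coefficient_set(-0.45, 210.5, -40, 0.8, "SBP"), model = "compensated"),
    dplyr::mutate(coefficient_set(-0.15, 103.25, -60, 3.5, "DBP"), model = "compensated"),
    dplyr::mutate(coefficient_set(-0.5, 215, 0, 0, "SBP"), model = "linear"),
    dplyr::mutate(coefficient_set(-0.2, 110, 0, 0, "DBP"), model = "linear"))
  prof <- calibration_profile("S07", ref, coeffs)
  path <- withr::local_tempfile(fileext = ".json")
  write_profile(prof, path)
  back <- read_profile(path)
  expect_equal(back$subject_id, "S07")
  expect_equal(back$reference$ptt0_ms, ref$ptt0_ms)
  expect_equal(dplyr::arrange(back$coefficients, model, pressure_type)$a,
               dplyr::arrange(prof$coefficients, model, pressure_type)$a)
})

test_that("estimate_session refuses invalid sessions and flags pressure inversions", {
  ref <- tibble::tibble(ptt0_ms = 200, pttv0_ms = 0)
  coeffs <- dplyr::bind_rows(
    dplyr::mutate(coefficient_set(-0.4, 200, 0, 0, "SBP"), model = "compensated"),
    dplyr::mutate(coefficient_set(-0.4, 205, 0, 0, "DBP"), model = "compensated"))
  prof <- calibration_profile("X", ref, coeffs)
  bad <- list(ptt = tibble::tibble(ptt_ms = rep(200, 12), beat_time_s = 1:12),
              validity = tibble::tibble(valid = FALSE, reason = "insufficient beats"))
  expect_error(estimate_session(bad, prof), class = "pttbp_invalid_session")
  ok <- tibble::tibble(ptt_ms = rep(200, 12), beat_time_s = as.numeric(1:12))
  expect_warning(out <- estimate_session(ok, prof), class = "pttbp_validation_warning")
  expect_false(any(out$pressure_order_ok))  # DBP coefficients exceed SBP here
  expect_equal(nrow(out), 8)
})
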