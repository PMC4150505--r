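test_that("measurement-difference branches resolve per the protocol", {
  r <- resolve_measurement_series(c(120, 123))
  expect_equal(r$status, "accepted_first")
  expect_equal(r$resolved, 120)

  r <- resolve_measurement_series(c(120, 127))
  expect_equal(r$status, "pending_third")
  expect_true(is.na(r$resolved))

  r <- resolve_measurement_series(c(120, 127, 122))
  expect_equal(r$status, "accepted_mean_of_three")
  expect_equal(r$resolved, 123)

  r <- resolve_measurement_series(c(120, 135))
  expect_equal(r$status, "discarded")
  expect_true(is.na(r$resolved))

  expect_error(resolve_measurement_series(120), class = "pttbp_parameter_error")
  expect_error(resolve_measurement_series(c(120, 121, 122, 123)),
               class = "pttbp_parameter_error")
})

test_that("boundary differences of exactly 5 and 10 mmHg take the third-measurement path", {
  expect_equal(resolve_measurement_series(c(120, 125))$status, "pending_third")
  expect_equal(resolve_measurement_series(c(120, 130))$status, "pending_third")
  expect_equal(resolve_measurement_series(c(120, 125, 121))$status, "accepted_mean_of_three")
  expect_equal(resolve_measurement_series(c(120, 130, 124))$status, "accepted_mean_of_three")
  expect_equal(resolve_measurement_series(c(120, 130.5))$status, "discarded")
  expect_equal(resolve_measurement_series(c(120, 124.9))$status, "accepted_first")
})

test_that("resolution is order-sensitive: the first measurement is positional", {
  expect_equal(resolve_measurement_series(c(118, 121))$resolved, 118)
  expect_equal(resolve_measurement_series(c(121, 118))$resolved, 121)
  m <- tibble::tibble(order_index = c(2, 1), sbp = c(121, 118), dbp = c(80, 78))
  expect_equal(resolve_reference_bp(m)$resolved_sbp, 118)  # sorts by order_index
})

test_that("session resolution applies the rule per pressure type, jointly conservative", {
  m <- tibble::tibble(order_index = 1:2, sbp = c(120, 122), dbp = c(80, 81))
  r <- resolve_reference_bp(m)
  expect_equal(r$status, "accepted_first")
  expect_equal(r$resolved_sbp, 120)
  expect_equal(r$resolved_dbp, 80)

  # SBP agrees, DBP needs a third measurement -> session pending
  m <- tibble::tibble(order_index = 1:2, sbp = c(120, 122), dbp = c(80, 87))
  expect_equal(resolve_reference_bp(m)$status, "pending_third")
  m3 <- tibble::tibble(order_index = 1:3, sbp = c(120, 122, 121), dbp = c(80, 87, 82))
  r <- resolve_reference_bp(m3)
  expect_equal(r$status, "accepted_mean_of_three")
  expect_equal(r$resolved_sbp, 120)            # SBP still resolves by its own rule
  expect_equal(r$resolved_dbp, mean(c(80, 87, 82)))

  # either type exceeding 10 mmHg discards the session
  m <- tibble::tibble(order_index = 1:2, sbp = c(120, 122), dbp = c(80, 95))
  r <- resolve_reference_bp(m)
  expect_equal(r$status, "discarded")
  expect_true(is.na(r$resolved_sbp))

  expect_error(resolve_reference_bp(tibble::tibble(order_index = 1:2,
                                                   sbp = c(120, 121), dbp = c(125, 80))),
               class = "pttbp_parameter_error")  # implausible dbp >= sbp
})

test_that("cohort validation counts analyzable subjects and datasets", {
  mk <- function(sid, valid = c(TRUE, TRUE, TRUE)) {
    tibble::tibble(subject_id = sid, session_label = SESSION_LABELS, valid = valid)
  }
  s <- validate_experiment(dplyr::bind_rows(mk("A"), mk("B", c(TRUE, TRUE, FALSE))))
  expect_equal(s$n_subjects, 2)
  expect_equal(s$n_analyzable, 1)
  expect_equal(s$n_datasets, 3)
  expect_match(s$subjects$failed_sessions[s$subjects$subject_id == "B"],
               "estimation_test")
  # an incomplete subject (missing a calibration posture) is never analyzable
  inc <- tibble::tibble(subject_id = "C",
                        session_label = c("calibration_sitting", "estimation_test"),
                        valid = TRUE)
  s <- validate_experiment(inc)
  expect_equal(s$n_analyzable, 0)
})

test_that("a programmed fluctuation burst excludes exactly that subject downstream", {
  cfg <- cohort_config(duration_s = 40, fluctuation_subjects = 2)
  co <- simulate_cohort(4, cfg, seed = 13)
  a <- analyze_cohort(co)
  s <- validate_experiment(a)
  expect_equal(s$n_subjects, 4)
  expect_equal(s$n_analyzable, 3)
  expect_equal(s$n_datasets, 9)
  bad <- dplyr::filter(s$subjects, !analyzable)
  expect_equal(bad$subject_id, "S02")
  expect_match(bad$failed_sessions, "estimation_test")
})
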