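# Independent brute-force oracles, written as explicit scalar arithmetic so
# they share no code path with the package implementations they check.

oracle_pttv <- function(w) {
  k <- length(w) - 1
  d <- numeric(k)
  for (i in seq_len(k)) d[i] <- w[i + 1] - w[i]
  m <- 0
  for (i in seq_len(k)) m <- m + d[i]
  m <- m / k
  ss <- 0
  for (i in seq_len(k)) ss <- ss + (d[i] - m)^2
  sqrt(ss / (k - 1))
}

oracle_vptt <- function(ptt, ptt0) (ptt - ptt0) / ptt0

oracle_bp <- function(a, b, c, d, mean_ptt, vptt, pttv, pttv0) {
  a * mean_ptt + b + c * vptt + d * (pttv - pttv0)
}

oracle_bland_altman <- function(est, ref) {
  n <- length(est)
  d <- numeric(n)
  for (i in seq_len(n)) d[i] <- est[i] - ref[i]
  m <- 0
  for (i in seq_len(n)) m <- m + d[i]
  m <- m / n
  ss <- 0
  for (i in seq_len(n)) ss <- ss + (d[i] - m)^2
  s <- sqrt(ss / (n - 1))
  list(mean = m, sd = s, lo = m - 1.96 * s, hi = m + 1.96 * s)
}

# Fraction of programmed events matched by a detection within `tol` samples
# (greedy nearest-neighbour match; each detection used at most once).
match_fraction <- function(detected, truth, tol) {
  if (!length(truth)) return(NA_real_)
  used <- logical(length(detected))
  hits <- 0
  for (t in truth) {
    if (!length(detected)) break
    d <- abs(detected - t)
    d[used] <- Inf
    j <- which.min(d)
    if (d[j] <= tol) {
      hits <- hits + 1
      used[j] <- TRUE
    }
  }
  hits / length(truth)
}

# Small noise-free, shared-coefficient cohort used across recovery tests.
recovery_cohort <- function(n_subjects, seed, duration_s = 60, render = TRUE,
                            ...) {
  cfg <- config_noise_free(cohort_config(duration_s = duration_s,
                                         shared_coefficients = TRUE, ...))
  simulate_cohort(n_subjects, cfg, seed = seed, render = render)
}

true_coeffs <- function(cohort, type) {
  dplyr::filter(cohort$subjects[[1]]$law$coeffs, pressure_type == type)
}
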