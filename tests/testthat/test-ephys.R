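test_that("decay_time recovers tau on a noiseless monoexponential", {
  # I(t) falls from a peak of 100 with tau = 0.39 s, sampled at 10 kHz
  tau <- 0.39
  t <- seq(0, 2.5, by = 1e-4)
  onset <- 0.5
  current <- ifelse(t < onset, 0, -100 * exp(-(t - onset) / tau))
  tr <- sweep_trace(t, current, baseline_window = c(0, 0.4),
                    pulse_onset_s = onset, sweep_id = "s1")
  d <- decay_time(tr)
  expect_true(d$crossed)
  expect_equal(d$peak_amplitude, 100)
  expect_equal(d$t_1e_s, tau, tolerance = 1e-4 / tau)  # within one sample
  # the fraction decayed at t_1e is 1 - 1/e ~ 63%
  expect_equal(round(100 * (1 - exp(-1))), 63)
  mag_at <- 100 * exp(-d$t_1e_s / tau)
  expect_equal(round(100 * (1 - mag_at / 100)), 63)
})

test_that("decay_time is scale invariant over amplitude and tau", {
  for (A in c(5, 500)) {
    for (tau in c(0.05, 0.39, 1.2)) {
      t <- seq(0, 0.3 + 6 * tau, by = 1e-4)
      cur <- ifelse(t < 0.3, 0, -A * exp(-(t - 0.3) / tau))
      tr <- sweep_trace(t, cur, c(0, 0.25), 0.3)
      d <- decay_time(tr)
      expect_equal(d$t_1e_s, tau, tolerance = 1e-4 / tau)
    }
  }
})

test_that("biexponential decay matches a root-finding oracle", {
  # I(t) = 60 exp(-t/0.2) + 40 exp(-t/0.8) from the peak
  t <- seq(0, 4, by = 1e-4)
  onset <- 0.5
  mag <- function(s) 60 * exp(-s / 0.2) + 40 * exp(-s / 0.8)
  cur <- ifelse(t < onset, 0, -mag(t - onset))
  tr <- sweep_trace(t, cur, c(0, 0.45), onset)
  d <- decay_time(tr)
  want <- uniroot(function(s) mag(s) - 100 / exp(1), c(0, 4), tol = 1e-10)$root
  expect_equal(d$t_1e_s, want, tolerance = 1e-4)
})

test_that("a trace that never decays to 1/e reports crossed = FALSE", {
  t <- seq(0, 1, by = 1e-3)
  cur <- ifelse(t < 0.2, 0, -100 * exp(-(t - 0.2) / 50))  # tau >> window
  tr <- sweep_trace(t, cur, c(0, 0.15), 0.2)
  d <- decay_time(tr)
  expect_false(d$crossed)
  expect_true(is.na(d$t_1e_s))
})

test_that("decay_time refuses a trace with no peak above noise", {
  set.seed(2)
  t <- seq(0, 1, by = 1e-3)
  cur <- rnorm(length(t), sd = 5)
  tr <- sweep_trace(t, cur, c(0, 0.45), 0.5)
  expect_error(decay_time(tr), "no peak above noise")
})

test_that("sweep averaging excludes uncrossed sweeps and reports the count", {
  res <- tibble::tibble(
    sweep_id = c("a", "b", "c"),
    peak_time_s = 0.5, peak_amplitude = 100,
    t_1e_s = c(0.40, 0.38, NA), crossed = c(TRUE, TRUE, FALSE)
  )
  avg <- average_sweeps(res)
  expect_equal(avg$mean_t_1e_s, 0.39)
  expect_equal(avg$n_excluded, 1)
  one <- average_sweeps(res[1, ])
  expect_equal(one$mean_t_1e_s, 0.40)
  none <- average_sweeps(res[3, ])
  expect_true(is.na(none$mean_t_1e_s))
})

test_that("dose-response normalization anchors the reference pH at 1", {
  peaks <- tibble::tibble(pH = c(7.0, 6.6, 6.0, 5.5),
                          peak = c(10, 50, 95, 100))
  dr <- normalize_dose_response(peaks)
  expect_equal(dr$normalized_response[dr$pH == 5.5], 1)
  expect_equal(dr$normalized_response[dr$pH == 6.6], 0.5)
  expect_error(normalize_dose_response(peaks[1:3, ]), "not present")
  bad <- tibble::tibble(pH = c(5.5, 7), peak = c(0, 1))
  expect_error(normalize_dose_response(bad), "positive")
})

test_that("noiseless Hill data are recovered to machine precision", {
  pH <- seq(7.0, 5.5, length.out = 8)
  truth <- list(pH05 = 6.6, n = -4.5)
  dr <- tibble::tibble(pH = pH,
                       normalized_response = hill_curve(pH, truth$pH05,
                                                        truth$n))
  fit <- fit_hill(dr)
  expect_true(fit$converged)
  expect_equal(fit$pH05, 6.6, tolerance = 1e-6)
  expect_equal(fit$hill_n, 4.5, tolerance = 1e-5)
  # fitted curve passes through 0.5 at the fitted midpoint, and is bounded
  expect_equal(hill_curve(fit$pH05, fit$pH05, fit$n), 0.5, tolerance = 1e-12)
  grid <- hill_curve(seq(0, 14, 0.05), fit$pH05, fit$n)
  expect_true(all(grid >= 0 & grid <= 1))
})

test_that("fit_hill shifts with the pH axis (scale consistency)", {
  pH <- seq(7.0, 5.5, length.out = 8)
  y <- hill_curve(pH, 6.6, -4.5) + c(0.01, -0.01)   # small fixed perturbation
  f1 <- fit_hill(tibble::tibble(pH = pH, normalized_response = y))
  delta <- 0.8
  f2 <- fit_hill(tibble::tibble(pH = pH + delta, normalized_response = y))
  expect_equal(f2$pH05 - f1$pH05, delta, tolerance = 1e-6)
  expect_equal(f2$hill_n, f1$hill_n, tolerance = 1e-6)
})

test_that("fit_hill rejects degenerate inputs", {
  flat <- tibble::tibble(pH = c(7, 6.5, 6, 5.5),
                         normalized_response = rep(0.4, 4))
  expect_error(fit_hill(flat), "degenerate")
  expect_error(fit_hill(flat[1:3, ]), "4 distinct")
})

test_that("seeded noisy dose-response recovery meets the stated tolerances", {
  set.seed(123)
  pH <- seq(7.0, 5.5, length.out = 8)
  errs_mid <- errs_n <- numeric(200)
  for (i in 1:200) {
    y <- hill_curve(pH, 6.6, -4.5) + rnorm(8, sd = 0.02)
    fit <- fit_hill(tibble::tibble(pH = pH, normalized_response = y))
    errs_mid[i] <- abs(fit$pH05 - 6.6)
    errs_n[i] <- abs(fit$hill_n - 4.5) / 4.5
  }
  expect_lt(median(errs_mid), 0.02)
  expect_lt(median(errs_n), 0.10)
})

test_that("wash-on time course normalizes to the first sweep", {
  expect_equal(washon_timecourse(c(50, 50, 50))$normalized_peak,
               rep(1, 3))
  tc <- washon_timecourse(c(40, 55, 70, 78, 80))
  expect_equal(tc$normalized_peak[1], 1)
  expect_equal(tc$normalized_peak[5], 2)
  expect_error(washon_timecourse(c(0, 10)), "positive")
  # saturating wash-on: exponential approach to a known plateau ratio
  sweep_idx <- 1:12
  peaks <- 30 * (1 + 1.5 * (1 - exp(-(sweep_idx - 1) / 2)))
  tc2 <- washon_timecourse(peaks)
  expect_equal(tail(tc2$normalized_peak, 1), 2.5, tolerance = 0.01)
})

test_that("sweep CSVs round-trip through the annotation sidecar", {
  spec <- ephys_spec(seed = 5)
  tr <- simulate_current(spec, 6.0, sweep_id = "s1", seed = 99)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "sweep.csv")
  readr::write_csv(tibble::tibble(time_s = tr$time_s,
                                  current_pA = tr$current), path)
  jsonlite::write_json(list(baseline_window = attr(tr, "baseline_window"),
                            pulse_onset_s = attr(tr, "pulse_onset_s"),
                            sweep_id = "s1", pH = 6.0),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  back <- read_sweep_csv(path)
  expect_equal(back$current, tr$current, tolerance = 1e-12)
  expect_equal(attr(back, "pH"), 6.0)
  d1 <- decay_time(tr); d2 <- decay_time(back)
  expect_equal(d2$t_1e_s, d1$t_1e_s)
})
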