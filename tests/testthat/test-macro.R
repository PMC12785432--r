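# build a macro_response by hand for descriptor closed-form checks
fake_response <- function(time, p_open, pulse_ms, washout_ms = 0) {
  conc <- if (washout_ms > 0) c(10, 0) else 10
  dur <- if (washout_ms > 0) c(pulse_ms, washout_ms) else pulse_ms
  pk <- gabakin:::refine_peak(time, p_open)
  structure(list(time = time, p_open = p_open,
                 protocol = pulse_protocol(conc, dur),
                 peak = pk$value, peak_time = pk$time),
            class = "macro_response")
}

test_that("rise time: linear ramp and exponential closed forms", {
  t <- seq(0, 2, by = 0.001)
  ramp <- fake_response(t, pmin(t, 1), 2)
  expect_equal(rise_time_10_90(ramp), 0.8, tolerance = 1e-3)

  tau <- 0.37
  t5 <- seq(0, 5, by = 0.001)
  expc <- fake_response(t5, 1 - exp(-t5 / tau), 5)
  expect_equal(rise_time_10_90(expc), tau * log(0.9 / 0.1), tolerance = 1e-2)

  flat <- fake_response(t, rep(0, length(t)), 2)
  expect_error(rise_time_10_90(flat), "undefined")
})

test_that("biexponential desensitization fit round-trips a generated curve", {
  t <- seq(0, 500, by = 0.1)
  y <- 0.6 * exp(-t / 3) + 0.2 * exp(-t / 130) + 0.2
  resp <- fake_response(t, y, 500)
  fit <- fit_desensitization(resp, window = c(0, 500))
  expect_true(fit$converged)
  expect_equal(fit$tau_fast, 3, tolerance = 1e-3)
  expect_equal(fit$tau_slow, 130, tolerance = 1e-3)
  expect_equal(fit$apct_fast, 0.6, tolerance = 1e-3)
  expect_equal(fit$apct_slow, 0.2, tolerance = 1e-3)

  # constant trace: amplitudes zero, offset = amplitude, flagged
  flat <- fake_response(t, rep(0.4, length(t)), 500)
  ffit <- fit_desensitization(flat, window = c(0, 500))
  expect_equal(ffit$a_fast, 0)
  expect_equal(ffit$a_slow, 0)
  expect_equal(ffit$c0, 0.4)
  expect_equal(ffit$apct_fast, 0)
  expect_true("constant_trace" %in% ffit$flags)
})

test_that("fraction remaining and deactivation closed forms", {
  t <- seq(0, 600, by = 0.05)
  resp <- fake_response(t, exp(-t / 100), 600)
  expect_equal(fraction_remaining(resp, 100), exp(-1), tolerance = 1e-4)
  expect_equal(fraction_remaining(resp, 0), 1, tolerance = 1e-6)
  expect_error(fraction_remaining(resp, 650), "beyond")

  # exact single exponential during washout
  tw <- seq(0, 2000, by = 0.5)
  resp2 <- fake_response(c(seq(0, 9.5, 0.5), 10 + tw),
                         c(rep(1, 20), exp(-tw / 100)), 10, 2000)
  dfit <- fit_deactivation(resp2)
  expect_true(dfit$converged)
  expect_equal(dfit$tau, 100, tolerance = 1e-3)
  expect_error(fit_deactivation(resp2, window = 5000), "exceeds")
})

test_that("descriptors are invariant to uniform amplitude rescaling", {
  t <- seq(0, 500, by = 0.05)
  y <- 0.4 * (0.6 * exp(-t / 3) + 0.2 * exp(-t / 130) + 0.2) *
    (1 - exp(-t / 0.2))
  for (sc in c(1, 7.3)) {
    r <- fake_response(t, sc * y, 500)
    if (sc == 1) {
      rt0 <- rise_time_10_90(r)
      d0 <- fit_desensitization(r)
      f0 <- fraction_remaining(r, 300)
    } else {
      expect_equal(rise_time_10_90(r), rt0, tolerance = 1e-9)
      d1 <- fit_desensitization(r)
      expect_equal(d1$tau_fast, d0$tau_fast, tolerance = 1e-6)
      expect_equal(d1$apct_fast, d0$apct_fast, tolerance = 1e-6)
      expect_equal(fraction_remaining(r, 300), f0, tolerance = 1e-9)
    }
  }
})

test_that("simulated saturating pulse behaves like the wild-type model", {
  resp <- simulate_pulse(scheme_full(), macro_rates_wt(), saturating_pulse())
  # rest -> fast sub-millisecond rise, biexponential sag, washout decay
  expect_lt(rise_time_10_90(resp), 1)
  expect_gt(resp$peak, 0.2)
  des <- fit_desensitization(resp)
  expect_true(des$converged)
  expect_lt(des$tau_fast, des$tau_slow)
  # anchors the model was tuned to reproduce (printed means, +-30%)
  expect_equal(des$apct_fast, 0.58, tolerance = 0.30)
  expect_equal(fraction_remaining(resp, 500 - resp$peak_time), 0.2,
               tolerance = 0.30)
  dea <- fit_deactivation(resp)
  expect_equal(dea$tau, 407.68, tolerance = 0.25)

  # FR from the fitted biexponential matches FR from the raw trace within 2%
  fr_fit <- (des$a_fast * exp(-300 / des$tau_fast) +
             des$a_slow * exp(-300 / des$tau_slow) + des$c0) / resp$peak
  expect_equal(fr_fit, fraction_remaining(resp, 300), tolerance = 0.02)

  # zero-concentration protocol from rest stays shut
  r0 <- simulate_pulse(scheme_full(), macro_rates_wt(),
                       pulse_protocol(0, 100))
  expect_lt(max(r0$p_open), 1e-12)
})

test_that("descriptors are stable under grid refinement", {
  base <- macro_kinetics(scheme_full(), macro_rates_wt(),
                         saturating_pulse())
  fine <- macro_kinetics(scheme_full(), macro_rates_wt(),
                         saturating_pulse(dt_fine = 0.005, dt_coarse = 0.05))
  for (col in c("peak", "rt", "tau_des_fast", "apct_des_fast", "fr500",
                "tau_dea"))
    expect_equal(fine[[col]], base[[col]], tolerance = 1e-3)
})

test_that("log-logistic fit: exact recovery, flat-data flag, binding-model EC50", {
  concs <- 10^seq(-3, 1, length.out = 9)
  a <- 0 + (1 - 0) / (1 + (0.04707 / concs)^1.2)
  fit <- fit_log_logistic(data.frame(conc = concs, amplitude = a))
  expect_true(fit$converged)
  expect_equal(fit$ec50, 0.04707, tolerance = 1e-4)
  expect_equal(fit$n_h, 1.2, tolerance = 1e-4)

  flat <- fit_log_logistic(data.frame(conc = concs,
                                      amplitude = rep(0.5, length(concs))))
  expect_false(flat$converged)
  expect_true("flat_data" %in% flat$flags)
  expect_error(fit_log_logistic(data.frame(conc = 1:3, amplitude = 1:3)),
               "at least 4")

  # two-state binding model: EC50 of the peak dose-response equals Kd
  kd <- 0.9 / 10
  curve <- dose_response_curve(binding_scheme(),
                               rate_set(c(k_on = 10, k_off = 0.9)),
                               10^seq(-3, 2, length.out = 11),
                               pulse_ms = 3000, washout_ms = 10)
  bfit <- fit_log_logistic(curve)
  expect_equal(bfit$ec50, kd, tolerance = 0.01)
  expect_error(dose_response_curve(binding_scheme(),
                                   rate_set(c(k_on = 10, k_off = 0.9)),
                                   numeric(0)), "empty")
})

test_that("saturating concentrations produce equal normalized amplitudes", {
  curve <- dose_response_curve(scheme_full(), macro_rates_wt(),
                               c(10, 20, 50), pulse_ms = 500)
  expect_true(all(curve$amplitude > 0.98))
})

test_that("rate scan: grid, identity row, k_off monotonicity, beta insensitivity", {
  expect_equal(scan_multipliers(),
               sort(c(0.05, 0.10, 0.15, 0.25, 0.50, 0.75, 1.0, 1.25, 1.50,
                      1.75, 2.0, 2.25, 2.5, 2.75, 3.0, 3.25, 3.5, 3.75, 4.0,
                      5.0, 7.5, 10.0)))
  expect_error(rate_scan(scheme_full(), macro_rates_wt(), "nope",
                         multipliers = 1), "unknown rate")

  # multiplier 1 equals the unperturbed run bit-for-bit
  scan1 <- rate_scan(scheme_full(), macro_rates_wt(), "k_off",
                     multipliers = c(0.5, 1.0))
  base <- macro_kinetics(scheme_full(), macro_rates_wt())
  row1 <- scan1$table[scan1$table$multiplier == 1, names(base)]
  rownames(row1) <- NULL; rownames(base) <- NULL
  expect_identical(unlist(row1), unlist(base))

  # deactivation accelerates monotonically with unbinding rate
  ko <- rate_scan(scheme_full(), macro_rates_wt(), "k_off",
                  multipliers = c(0.25, 0.5, 1, 2, 4, 10))
  expect_true(all(diff(ko$table$tau_dea) < 0))

  # gating (opening) rate leaves deactivation nearly untouched
  bo <- suppressWarnings(rate_scan(scheme_full(), macro_rates_wt(), "beta",
                                   multipliers = scan_multipliers()))
  expect_lt(max(bo$table$tau_dea, na.rm = TRUE) /
            min(bo$table$tau_dea, na.rm = TRUE), 2)
})
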