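#' Agonist pulse protocols
#'
#' A protocol is an ordered sequence of constant-concentration epochs
#' (concentration in mM, duration in ms). The sampling grid is dense
#' (`dt_fine`) for the first `fine_span` ms of each epoch to resolve the
#' sub-millisecond rising phase, then coarser (`dt_coarse`); descriptor
#' extraction is insensitive to further refinement.
#'
#' @param conc numeric vector of epoch concentrations (mM).
#' @param duration numeric vector of epoch durations (ms, positive).
#' @param dt_fine,dt_coarse sampling steps (ms).
#' @param fine_span span sampled at `dt_fine` at each epoch start (ms).
#' @return Object of class `pulse_protocol`.
#' @export
pulse_protocol <- function(conc, duration, dt_fine = 0.01, dt_coarse = 0.1,
                           fine_span = 10) {
  stopifnot(length(conc) == length(duration), length(conc) >= 1)
  if (any(duration <= 0)) stop("epoch durations must be positive")
  if (any(conc < 0)) stop("concentrations must be non-negative")
  structure(list(conc = conc, duration = duration, dt_fine = dt_fine,
                 dt_coarse = dt_coarse, fine_span = fine_span),
            class = "pulse_protocol")
}

#' @rdname pulse_protocol
#' @param pulse_conc,pulse_ms,washout_ms,baseline_ms the canonical activation
#'   protocol: a zero-agonist baseline (so the simulation starts from rest),
#'   a single agonist pulse, and washout.
#' @param ... passed on to [pulse_protocol()].
#' @export
saturating_pulse <- function(pulse_conc = 10, pulse_ms = 500,
                             washout_ms = 2000, baseline_ms = 1, ...) {
  pulse_protocol(c(0, pulse_conc, 0), c(baseline_ms, pulse_ms, washout_ms),
                 ...)
}

protocol_times <- function(p, i) {
  dur <- p$duration[i]
  fine <- seq(0, min(p$fine_span, dur), by = p$dt_fine)
  if (dur > p$fine_span)
    unique(c(fine, seq(min(p$fine_span, dur), dur, by = p$dt_coarse), dur))
  else unique(c(fine, dur))
}

# end of the last non-zero-concentration epoch, i.e. start of washout (ms)
protocol_t_off <- function(p) {
  nz <- which(p$conc > 0)
  if (!length(nz)) return(NA_real_)
  sum(p$duration[seq_len(max(nz))])
}

# start of the first non-zero-concentration epoch (agonist application, ms)
protocol_t_on <- function(p) {
  nz <- which(p$conc > 0)
  if (!length(nz)) return(NA_real_)
  if (min(nz) == 1) 0 else sum(p$duration[seq_len(min(nz) - 1)])
}

#' Simulate a macroscopic response to an agonist pulse protocol
#'
#' Starts from equilibrium at the first epoch's concentration (canonically
#' 0 mM, the resting state) and relaxes the occupancy vector through the
#' protocol's epochs via [relax()]. The macroscopic observable is the summed
#' open-class occupancy P_open(t), the normalized current analogue.
#'
#' @param scheme a [kinetic_scheme()].
#' @param rates a [rate_set()].
#' @param protocol a [pulse_protocol()].
#' @return Object of class `macro_response`: list with `time`, `p_open`,
#'   `occupancy` (full trajectory), `protocol`, `peak` (parabolically refined
#'   maximum) and `peak_time`.
#' @export
simulate_pulse <- function(scheme, rates, protocol) {
  stopifnot(inherits(protocol, "pulse_protocol"))
  q0 <- build_q(scheme, rates, protocol$conc[1])
  p0 <- tryCatch(equilibrium(q0),
                 error = function(e) equilibrium(q0, component_of = scheme$states[1]))
  segs <- lapply(seq_along(protocol$conc), function(i)
    list(q = build_q(scheme, rates, protocol$conc[i]),
         duration = protocol$duration[i],
         times = protocol_times(protocol, i)))
  traj <- relax(segs, p0)
  po <- open_probability(traj, scheme)
  pk <- refine_peak(traj$time, po)
  structure(list(time = traj$time, p_open = po, occupancy = traj,
                 protocol = protocol, peak = pk$value, peak_time = pk$time),
            class = "macro_response")
}

#' @export
print.macro_response <- function(x, ...) {
  cat("Macroscopic response:", length(x$time), "samples over",
      round(max(x$time), 1), "ms; peak P_open",
      signif(x$peak, 4), "at", round(x$peak_time, 3), "ms\n")
  invisible(x)
}

# global maximum on the sampled grid with parabolic refinement through the
# three samples around it (descriptor stability under grid changes)
refine_peak <- function(t, y) {
  i <- which.max(y)
  if (i == 1 || i == length(y)) return(list(time = t[i], value = y[i]))
  t3 <- t[(i - 1):(i + 1)]; y3 <- y[(i - 1):(i + 1)]
  d <- (y3[1] - 2 * y3[2] + y3[3])
  if (abs(d) < .Machine$double.eps) return(list(time = t[i], value = y[i]))
  # vertex of the parabola through the three points (uniform or not)
  a <- cbind(t3^2, t3, 1)
  cf <- solve(a, y3)
  tv <- -cf[2] / (2 * cf[1])
  if (cf[1] < 0 && tv >= t3[1] && tv <= t3[3])
    list(time = unname(tv), value = unname(cf[1] * tv^2 + cf[2] * tv + cf[3]))
  else list(time = unname(t[i]), value = unname(y[i]))
}

#' 10-90% rise time
#'
#' Time between the first crossings of 10% and 90% of the peak amplitude on
#' the rising limb, with linear interpolation between samples.
#'
#' @param resp a `macro_response` (or any list with `time`, `p_open`,
#'   `peak`, `peak_time`).
#' @return Rise time in ms.
#' @export
rise_time_10_90 <- function(resp) {
  pk <- resp$peak
  if (!is.finite(pk) || pk <= 0 || diff(range(resp$p_open)) < 1e-12 * max(pk, 1))
    stop("rise time undefined: response has no positive peak")
  sel <- resp$time <= resp$peak_time
  t <- resp$time[sel]; y <- resp$p_open[sel]
  t10 <- first_crossing(t, y, 0.1 * pk)
  t90 <- first_crossing(t, y, 0.9 * pk)
  if (is.na(t10) || is.na(t90))
    stop("rise time undefined: rising limb does not cross 10%/90% of peak")
  unname(t90 - t10)
}

first_crossing <- function(t, y, level) {
  above <- y >= level
  i <- which(above)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1) return(t[1])
  t[i - 1] + (level - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
}

#' Biexponential fit of macroscopic desensitization
#'
#' Fits `A_f exp(-t/tau_f) + A_s exp(-t/tau_s) + C` (all amplitudes and the
#' offset non-negative) to P_open from the peak to the end of the agonist
#' pulse, with t re-zeroed at the peak. Components are ordered so that
#' `tau_fast <= tau_slow`. Percentages use the offset in the denominator:
#' `A%_fast = A_f / (A_f + A_s + C)` and likewise for the slow component.
#'
#' Non-convergence is reported in the `converged`/`flags` fields rather than
#' as an error; an effectively mono-exponential decay pins the slow amplitude
#' near zero and is flagged `"mono_exponential"`.
#'
#' @param resp a `macro_response`.
#' @param window numeric length 2, fit window in ms (defaults to peak to
#'   pulse end).
#' @return List: `tau_fast`, `tau_slow`, `a_fast`, `a_slow`, `c0`,
#'   `apct_fast`, `apct_slow`, `converged`, `flags`, `rss`.
#' @export
fit_desensitization <- function(resp, window = NULL) {
  t_off <- protocol_t_off(resp$protocol)
  if (is.null(window)) window <- c(resp$peak_time, t_off)
  sel <- resp$time >= window[1] & resp$time <= window[2]
  if (sum(sel) < 10)
    stop("desensitization window must span at least 10 samples after the peak")
  if (diff(window) < 100)
    warning("pulse shorter than 100 ms: slow component poorly constrained")
  td <- unname(resp$time[sel] - window[1])
  y <- unname(resp$p_open[sel])
  amp <- y[1]
  flags <- character()
  if (diff(range(y)) < 1e-12 * max(amp, 1)) {
    return(list(tau_fast = NA_real_, tau_slow = NA_real_, a_fast = 0,
                a_slow = 0, c0 = amp, apct_fast = 0, apct_slow = 0,
                converged = TRUE, flags = "constant_trace", rss = 0))
  }
  span <- max(td)
  starts <- list(
    list(Af = 0.5 * amp, tf = span / 100, As = 0.2 * amp, ts = span / 3, C = 0.2 * amp),
    list(Af = 0.6 * amp, tf = span / 30,  As = 0.2 * amp, ts = span,     C = 0.1 * amp),
    list(Af = 0.3 * amp, tf = span / 300, As = 0.3 * amp, ts = span / 10, C = 0.3 * amp))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ Af * exp(-td / tf) + As * exp(-td / ts) + C,
                        start = s, lower = c(0, 1e-6, 0, 1e-6, 0),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    return(list(tau_fast = NA_real_, tau_slow = NA_real_, a_fast = NA_real_,
                a_slow = NA_real_, c0 = NA_real_, apct_fast = NA_real_,
                apct_slow = NA_real_, converged = FALSE,
                flags = "no_convergence", rss = NA_real_))
  cf <- coef(best$fit)
  comps <- cbind(a = c(cf[["Af"]], cf[["As"]]), tau = c(cf[["tf"]], cf[["ts"]]))
  comps <- comps[order(comps[, "tau"]), , drop = FALSE]
  denom <- sum(comps[, "a"]) + cf[["C"]]
  apct <- if (denom > 0) comps[, "a"] / denom else c(0, 0)
  if (comps[2, "a"] < 1e-6 * max(amp, 1)) flags <- c(flags, "mono_exponential")
  list(tau_fast = unname(comps[1, "tau"]), tau_slow = unname(comps[2, "tau"]),
       a_fast = unname(comps[1, "a"]), a_slow = unname(comps[2, "a"]),
       c0 = unname(cf[["C"]]),
       apct_fast = unname(apct[1]), apct_slow = unname(apct[2]),
       converged = TRUE, flags = flags, rss = best$rss)
}

#' Fraction of the peak response remaining after a given time
#'
#' `FR_t = Amp(t_peak + t) / Amp_max`, linearly interpolated on the sampled
#' trace. `t` must not extend beyond the end of the agonist pulse.
#'
#' @param resp a `macro_response`.
#' @param t_after_peak time after the peak, ms.
#' @return Fraction in `[0, 1]`.
#' @export
fraction_remaining <- function(resp, t_after_peak) {
  t_off <- protocol_t_off(resp$protocol)
  target <- resp$peak_time + t_after_peak
  if (is.na(t_off) || target > t_off + 1e-9)
    stop("fraction remaining requested beyond the end of the pulse")
  y <- approx(resp$time, resp$p_open, xout = target, ties = "ordered")$y
  unname(y / resp$peak)
}

#' Single-exponential fit of deactivation
#'
#' Fits `A exp(-t/tau)` (no offset) to P_open after agonist removal, with t
#' re-zeroed at the start of the washout epoch. The default window is the
#' first 2000 ms of washout.
#'
#' @param resp a `macro_response` whose protocol contains a washout epoch.
#' @param window fit window length after agonist removal (ms).
#' @return List: `tau` (ms), `a`, `converged`, `rss`.
#' @export
fit_deactivation <- function(resp, window = 2000) {
  t_off <- protocol_t_off(resp$protocol)
  if (is.na(t_off) || t_off >= max(resp$time))
    stop("protocol has no washout epoch after the pulse")
  if (t_off + window > max(resp$time) + 1e-9)
    stop("deactivation window exceeds the simulated span")
  sel <- resp$time >= t_off & resp$time <= t_off + window
  tw <- resp$time[sel] - t_off
  y <- resp$p_open[sel]
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-tw / tau),
                      start = list(A = max(y[1], 1e-12), tau = window / 5),
                      lower = c(0, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(tau = NA_real_, a = NA_real_, converged = FALSE, rss = NA_real_))
  cf <- coef(fit)
  list(tau = unname(cf[["tau"]]), a = unname(cf[["A"]]), converged = TRUE,
       rss = sum(residuals(fit)^2))
}

#' All macroscopic kinetic descriptors of one simulated response
#'
#' Convenience wrapper running [simulate_pulse()] and extracting the full
#' descriptor row: peak, 10-90% rise time, biexponential desensitization
#' (time constants and percentages), fractions remaining at 10/300/500 ms,
#' and the deactivation time constant.
#'
#' @inheritParams simulate_pulse
#' @param fr_times times after the start of agonist application for
#'   fraction-remaining readouts (ms); with the canonical 500 ms pulse,
#'   `fr500` reads the trace exactly at pulse end.
#' @return One-row data frame of descriptors.
#' @export
macro_kinetics <- function(scheme, rates, protocol = saturating_pulse(),
                           fr_times = c(10, 300, 500)) {
  resp <- simulate_pulse(scheme, rates, protocol)
  des_na <- list(tau_fast = NA_real_, tau_slow = NA_real_,
                 apct_fast = NA_real_, apct_slow = NA_real_,
                 converged = FALSE)
  des <- tryCatch(fit_desensitization(resp), error = function(e) des_na)
  dea <- tryCatch(fit_deactivation(resp),
                  error = function(e) list(tau = NA_real_, converged = FALSE))
  t_on <- protocol_t_on(protocol)
  fr <- vapply(fr_times, function(tt)
    tryCatch(fraction_remaining(resp, t_on + tt - resp$peak_time),
             error = function(e) NA_real_),
    numeric(1))
  out <- data.frame(peak = resp$peak, rt = rise_time_10_90(resp),
                    tau_des_fast = des$tau_fast, tau_des_slow = des$tau_slow,
                    apct_des_fast = des$apct_fast, apct_des_slow = des$apct_slow,
                    tau_dea = dea$tau,
                    des_converged = des$converged, dea_converged = dea$converged)
  fr_df <- as.data.frame(as.list(setNames(fr, paste0("fr", fr_times))))
  cbind(out[1], fr_df, out[-1])
}

#' Dose-response curve of normalized peak responses
#'
#' Simulates the pulse protocol at each concentration and reports the peak
#' open probability normalized to the maximum across concentrations.
#'
#' @inheritParams simulate_pulse
#' @param concs agonist concentrations in mM (non-empty).
#' @param pulse_ms,washout_ms protocol template applied at each concentration.
#' @return Object of class `dose_response_curve`: data frame with `conc`,
#'   `peak`, `amplitude` (normalized).
#' @export
dose_response_curve <- function(scheme, rates, concs, pulse_ms = 500,
                                washout_ms = 200) {
  if (length(concs) == 0) stop("concentration list is empty")
  if (any(concs <= 0)) stop("dose-response concentrations must be positive")
  peaks <- vapply(concs, function(cc)
    simulate_pulse(scheme, rates,
                   saturating_pulse(cc, pulse_ms, washout_ms))$peak,
    numeric(1))
  structure(data.frame(conc = concs, peak = peaks,
                       amplitude = peaks / max(peaks)),
            class = c("dose_response_curve", "data.frame"))
}

#' Four-parameter log-logistic (Hill) fit of a dose-response curve
#'
#' Nonlinear least squares of
#' `A = A_min + (A_max - A_min) / (1 + (EC50 / c)^n_H)`,
#' parameterized on log-concentration (EC50 enters as `log(EC50)`), giving
#' the half-maximal concentration and the Hill slope.
#'
#' @param curve a [dose_response_curve()] or data frame with `conc` and
#'   `amplitude` (needs at least 4 points).
#' @return Object of class `log_logistic_fit`: list with `a_max`, `a_min`,
#'   `ec50` (mM), `n_h`, `converged`, `flags`, `vcov`.
#' @export
fit_log_logistic <- function(curve) {
  if (nrow(curve) < 4) stop("log-logistic fit needs at least 4 points")
  lc <- log(curve$conc)
  a <- curve$amplitude
  flags <- character()
  if (diff(range(a)) < 1e-10 * max(abs(a), 1))
    return(structure(list(a_max = max(a), a_min = min(a), ec50 = NA_real_,
                          n_h = NA_real_, converged = FALSE,
                          flags = "flat_data", vcov = NULL),
                     class = "log_logistic_fit"))
  lec0 <- approx(a + seq_along(a) * 1e-12, lc,
                 xout = min(a) + 0.5 * diff(range(a)), rule = 2,
                 ties = "ordered")$y
  fit <- tryCatch(
    minpack.lm::nlsLM(a ~ Amin + (Amax - Amin) / (1 + exp(nh * (lec - lc))),
                      start = list(Amin = min(a), Amax = max(a),
                                   lec = lec0, nh = 1.2),
                      lower = c(-Inf, -Inf, -Inf, 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit))
    return(structure(list(a_max = NA_real_, a_min = NA_real_, ec50 = NA_real_,
                          n_h = NA_real_, converged = FALSE,
                          flags = "no_convergence", vcov = NULL),
                     class = "log_logistic_fit"))
  cf <- coef(fit)
  vc <- tryCatch(vcov(fit), error = function(e) NULL)
  structure(list(a_max = unname(cf[["Amax"]]), a_min = unname(cf[["Amin"]]),
                 ec50 = exp(unname(cf[["lec"]])), n_h = unname(cf[["nh"]]),
                 converged = TRUE, flags = flags, vcov = vc),
            class = "log_logistic_fit")
}

#' @export
print.log_logistic_fit <- function(x, ...) {
  cat("Log-logistic fit: EC50 =", signif(x$ec50, 4), "mM, n_H =",
      signif(x$n_h, 3), "\n")
  invisible(x)
}

#' The published rate-perturbation multiplier grid
#'
#' The 21 scan multipliers (0.05-10x) used for systematic single-rate
#' perturbation, plus the unperturbed 1.0.
#' @return Sorted numeric vector of 22 multipliers.
#' @export
scan_multipliers <- function() {
  sort(c(0.05, 0.10, 0.15, 0.25, 0.50, 0.75, 1.0, 1.25, 1.50, 1.75, 2.0,
         2.25, 2.5, 2.75, 3.0, 3.25, 3.5, 3.75, 4.0, 5.0, 7.5, 10.0))
}

#' Systematic perturbation scan of one rate constant
#'
#' Re-simulates the pulse protocol with the named rate scaled by each
#' multiplier and extracts the full macroscopic descriptor table, mapping how
#' each kinetic feature depends on the perturbed rate. The multiplier-1 row
#' is computed through the identical code path as the unperturbed model and
#' is therefore bitwise identical to it.
#'
#' @inheritParams simulate_pulse
#' @param rate_name name of the rate to scale (must exist in `rates`).
#' @param multipliers numeric vector of scale factors
#'   (default [scan_multipliers()]).
#' @return Object of class `rate_scan`: list with `rate_name` and `table`
#'   (descriptor data frame with a `multiplier` column).
#' @export
rate_scan <- function(scheme, rates, rate_name,
                      multipliers = scan_multipliers(),
                      protocol = saturating_pulse()) {
  if (!rate_name %in% names(rates))
    stop("unknown rate: ", rate_name)
  rows <- lapply(multipliers, function(m) {
    r2 <- rates
    r2[[rate_name]] <- r2[[rate_name]] * m
    cbind(multiplier = m, macro_kinetics(scheme, r2, protocol))
  })
  structure(list(rate_name = rate_name, table = do.call(rbind, rows)),
            class = "rate_scan")
}

#' @export
print.rate_scan <- function(x, ...) {
  cat("Rate scan of", x$rate_name, "over", nrow(x$table), "multipliers\n")
  print(x$table[, c("multiplier", "rt", "tau_des_fast", "fr500", "tau_dea")],
        row.names = FALSE)
  invisible(x)
}
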