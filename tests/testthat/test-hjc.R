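test_that("ideal-resolution densities are the scheme's exponential mixtures", {
  m0 <- apparent_model(scheme_gating(), sc_rates("WT"), 0)
  tt <- c(0.05, 0.3, 1, 3, 8)
  # single open state: exact single exponential with rate alpha2
  expect_equal(apparent_density(m0, "open", tt), 1.49 * exp(-1.49 * tt),
               tolerance = 1e-12)
  mix <- ideal_mixture(m0, "shut")
  expect_equal(mix$k, 4)
  # shortest shut time constant is close to the flipped-state lifetime
  # 1/(gamma + beta2 + d2 + d2p); return-coupling to the other shut states
  # shifts the exact eigenvalue by a few percent
  expect_equal(mix$components$tau[1], 1 / (7.76 + 27.25 + 1.17 + 0.12),
               tolerance = 0.05)
  expect_equal(sum(mix$components$p), 1, tolerance = 1e-9)
  # ideal mean open time = 1/alpha2
  expect_equal(apparent_mean(m0, "open"), 1 / 1.49, tolerance = 1e-6)
})

test_that("apparent densities integrate to one at finite dead time", {
  m <- apparent_model(scheme_gating(), sc_rates("WT"), 0.07)
  expect_lt(abs(integrate_apparent(m, "open") - 1), 1e-6)
  expect_lt(abs(integrate_apparent(m, "shut") - 1), 1e-6)
  expect_error(apparent_density(m, "open", 0.05), "unobservable")
  # missed brief shuttings concatenate openings: apparent mean open exceeds
  # the ideal mean open time
  expect_gt(apparent_mean(m, "open"), 1 / 1.49)
})

test_that("apparent densities converge to ideal densities as tau_d -> 0", {
  # the shut density has values ~25/ms and slopes ~1000/ms^2, so the
  # inherent difference at tau_d = 1e-6 ms is ~1e-3; a dead time of 1e-8 ms
  # probes the limit at the 1e-4 sup-norm level
  m0 <- apparent_model(scheme_gating(), sc_rates("WT"), 0)
  meps <- apparent_model(scheme_gating(), sc_rates("WT"), 1e-8)
  tt <- exp(seq(log(2e-5), log(50), length.out = 120))
  for (cl in c("open", "shut")) {
    d0 <- apparent_density(m0, cl, tt)
    d1 <- apparent_density(meps, cl, tt)
    expect_lt(max(abs(d0 - d1)), 1e-4)
  }
})

test_that("two-state apparent means match brute-force simulation within 3 SE", {
  set.seed(71)
  sch <- two_state_scheme()
  rates <- rate_set(c(a = 1.3, b = 4.0))
  tau <- 0.1
  q <- build_q(sch, rates, 0)
  ev <- gabakin:::sample_events(q, "O", 2e5, tau, equilibrium(q))
  m <- apparent_model(sch, rates, tau)
  for (cl in c("open", "shut")) {
    x <- ev$duration_ms[ev$class == (cl == "open")]
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - apparent_mean(m, cl)), 3 * se)
  }
})

test_that("apparent mean times match simulation for every genotype", {
  for (g in c("WT", "E153K", "E153A")) {
    set.seed(72)
    ev <- simulate_apparent_events(sc_rates(g), 1.2e5, 0.07)
    m <- apparent_model(scheme_gating(), sc_rates(g), 0.07)
    for (cl in c("open", "shut")) {
      x <- ev$duration_ms[ev$class == (cl == "open")]
      se <- sd(x) / sqrt(length(x))
      expect_lt(abs(mean(x) - apparent_mean(m, cl)), 3 * se)
    }
  }
})

test_that("likelihood: additivity, resolution check, ideal-limit equivalence", {
  set.seed(73)
  ev <- simulate_apparent_events(sc_rates("WT"), 400, 0.07)
  m <- apparent_model(scheme_gating(), sc_rates("WT"), 0.07)
  ll1 <- cluster_log_likelihood(ev, m)
  dup <- event_list(rep(ev$class, 2), rep(ev$duration_ms, 2),
                    cluster_id = rep(1:2, each = nrow(ev)),
                    resolution = 0.07)
  expect_equal(cluster_log_likelihood(dup, m), 2 * ll1, tolerance = 1e-10)
  expect_error(cluster_log_likelihood(ev,
    apparent_model(scheme_gating(), sc_rates("WT"), 0.05)), "does not match")

  # tau_d = 0: equals a direct aggregated-Markov likelihood computed
  # independently, on both a two-state and the five-state scheme
  set.seed(74)
  sch2 <- two_state_scheme()
  r2 <- rate_set(c(a = 1.1, b = 2.7))
  p <- sample_trajectory(build_q(sch2, r2, 0), "O", n_transitions = 600)
  ev2 <- aggregate_classes(p, sch2)
  m2 <- apparent_model(sch2, r2, 0)
  expect_equal(cluster_log_likelihood(ev2, m2),
               ideal_loglik_oracle(ev2, sch2, r2), tolerance = 1e-6)

  p5 <- sample_trajectory(build_q(scheme_gating(), sc_rates("E153K"), 0),
                          equilibrium(build_q(scheme_gating(),
                                              sc_rates("E153K"), 0)),
                          n_transitions = 1500)
  ev5 <- aggregate_classes(p5, scheme_gating())
  m5 <- apparent_model(scheme_gating(), sc_rates("E153K"), 0)
  expect_equal(cluster_log_likelihood(ev5, m5),
               ideal_loglik_oracle(ev5, scheme_gating(), sc_rates("E153K")),
               tolerance = 1e-6)
})

test_that("true rates beat perturbed rates in likelihood on simulated data", {
  set.seed(75)
  ev <- simulate_apparent_events(sc_rates("WT"), 1e4, 0.07)
  m_true <- apparent_model(scheme_gating(), sc_rates("WT"), 0.07)
  half <- sc_rates("WT")
  v <- setNames(as.numeric(half), names(half)); v["beta2"] <- v["beta2"] / 2
  m_half <- apparent_model(scheme_gating(), rate_set(v), 0.07)
  expect_gt(cluster_log_likelihood(ev, m_true),
            cluster_log_likelihood(ev, m_half))
})

test_that("the optimizer never degrades the starting log-likelihood", {
  set.seed(76)
  ev <- simulate_apparent_events(sc_rates("WT"), 2000, 0.07)
  fit <- fit_gating_rates(ev, init = sc_rates("WT"), restarts = 1,
                          max_rounds = 2)
  expect_gte(fit$logLik, fit$logLik_init)
  expect_warning(fit_gating_rates(simulate_apparent_events(sc_rates("WT"),
                                                           400, 0.07),
                                  restarts = 1, max_rounds = 1),
                 "fewer than 1000")
})

test_that("predicted distributions carry experimental and ideal resolutions", {
  set.seed(77)
  fit <- list(scheme = scheme_gating(), rates = sc_rates("WT"), tau_d = 0.07)
  pd <- predicted_distributions(fit, n = 50)
  expect_setequal(unique(pd$resolution), c("experimental", "ideal"))
  expect_setequal(unique(pd$class), c("open", "shut"))
  expect_true(all(pd$density >= 0))
  # ideal-resolution open curve is the plain exponential
  po <- pd[pd$class == "open" & pd$resolution == "ideal", ]
  expect_equal(po$density, 1.49 * exp(-1.49 * po$t), tolerance = 1e-9)
})
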