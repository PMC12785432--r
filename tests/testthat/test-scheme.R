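test_that("Q-matrix assembly follows rates, statistical factors and concentration", {
  sch <- scheme_full()
  q10 <- build_q(sch, macro_rates_wt(), 10)
  expect_equal(q10["A2R", "A2F"], 5.0)              # flipping rate
  expect_equal(q10["R", "A1R"], 2 * 10 * 10)        # 2 * k_on * c, per-site
  expect_equal(q10["A1R", "A2R"], 10 * 10)
  expect_equal(q10["A2R", "A1R"], 2 * 0.9)
  expect_equal(unname(rowSums(q10)), rep(0, 7), tolerance = 1e-12)

  # zero concentration: binding entries vanish, rows still close
  q0 <- build_q(sch, macro_rates_wt(), 0)
  expect_equal(q0["R", "A1R"], 0)
  expect_equal(q0["A1R", "A2R"], 0)
  expect_equal(unname(rowSums(q0)), rep(0, 7), tolerance = 1e-12)

  # single-channel scheme, published WT rates
  qg <- build_q(scheme_gating(), sc_rates("WT"), 0)
  expect_equal(qg["A2F", "A2O"], 27.25)
  expect_equal(qg["A2O", "A2F"], 1.49)

  # alternative factor convention is a config switch
  q1111 <- build_q(scheme_full(binding_factors = c(1, 1, 1, 1)),
                   macro_rates_wt(), 10)
  expect_equal(q1111["R", "A1R"], 100)

  expect_error(build_q(sch, sc_rates("WT"), 10), "lacks")
  expect_error(build_q(sch, macro_rates_wt(), -1), "non-negative")
})

test_that("scheme invariants are enforced", {
  edges <- data.frame(from = "S", to = "O", rate = "b",
                      conc_dep = FALSE, factor = 1)
  expect_error(kinetic_scheme(c("S", "O"), "O", edges), "reverse")
  expect_error(two_state_scheme()$nothing, NA)
  expect_error(kinetic_scheme(c("S", "O"), c("S", "O"),
                              two_state_scheme()$edges), "strict subset")
  disconnected <- rbind(two_state_scheme()$edges,
                        data.frame(from = "X", to = "Y", rate = "c",
                                   conc_dep = FALSE, factor = 1),
                        data.frame(from = "Y", to = "X", rate = "c",
                                   conc_dep = FALSE, factor = 1))
  expect_error(kinetic_scheme(c("S", "O", "X", "Y"), "O", disconnected),
               "not connected")
  expect_error(rate_set(c(a = 1, b = -2)), "positive")
})

test_that("equilibrium matches the detailed-balance tree oracle", {
  for (g in c("WT", "E153K", "E153A")) {
    q <- build_q(scheme_gating(), sc_rates(g), 0)
    p <- equilibrium(q)
    oracle <- tree_equilibrium_oracle(scheme_gating(), sc_rates(g))
    expect_equal(p, oracle, tolerance = 1e-10)
  }
  # frozen oracle values for the open-state occupancy
  p_open <- vapply(c("WT", "E153K", "E153A"), function(g)
    equilibrium(build_q(scheme_gating(), sc_rates(g), 0))[["A2O"]],
    numeric(1))
  expect_equal(unname(p_open), c(0.78727, 0.76470, 0.49683), tolerance = 1e-4)

  # 7-state scheme at saturating agonist, against the same oracle
  q <- build_q(scheme_full(), macro_rates_wt(), 10)
  expect_equal(equilibrium(q),
               tree_equilibrium_oracle(scheme_full(), macro_rates_wt(), 10),
               tolerance = 1e-10)
})

test_that("reducible generators error unless restricted to a component", {
  sch <- kinetic_scheme(c("A", "B"), "B", rbind(
    data.frame(from = "A", to = "B", rate = "kon", conc_dep = TRUE, factor = 1),
    data.frame(from = "B", to = "A", rate = "koff", conc_dep = TRUE, factor = 1)))
  q0 <- build_q(sch, rate_set(c(kon = 1, koff = 2)), 0)  # all rates vanish
  expect_error(equilibrium(q0), "reducible")
  p <- equilibrium(q0, component_of = "A")
  expect_equal(unname(p["A"]), 1)
})

test_that("relax reproduces closed forms and conserves occupancy", {
  # constant generator Q = 0: trajectory stays at p0
  qz <- structure(matrix(0, 2, 2, dimnames = list(c("S", "O"), c("S", "O"))),
                  class = c("q_matrix", "matrix"))
  tr <- relax(list(list(q = qz, duration = 5)), c(0.3, 0.7), dt = 1)
  expect_equal(tr$S, rep(0.3, nrow(tr)))
  expect_equal(tr$O, rep(0.7, nrow(tr)))

  # symmetric two-state: P_open(inf) = 1/2 from any start
  q <- build_q(two_state_scheme(), rate_set(c(a = 1, b = 1)), 0)
  tr <- relax(list(list(q = q, duration = 50)), c(1, 0), dt = 0.5)
  expect_equal(tail(tr$O, 1), 0.5, tolerance = 1e-9)

  # closed form b/(a+b) * (1 - exp(-(a+b) t)) from the shut state
  a <- 1.7; b <- 0.6
  q <- build_q(two_state_scheme(), rate_set(c(a = a, b = b)), 0)
  tr <- relax(list(list(q = q, duration = 4)), c(1, 0), dt = 0.05)
  expect_equal(tr$O, b / (a + b) * (1 - exp(-(a + b) * tr$time)),
               tolerance = 1e-9)

  # occupancy conservation through a full pulse + washout of the 7-state model
  segs <- list(list(q = build_q(scheme_full(), macro_rates_wt(), 10),
                    duration = 100),
               list(q = build_q(scheme_full(), macro_rates_wt(), 0),
                    duration = 500))
  tr <- relax(segs, c(1, rep(0, 6)), dt = 0.5)
  sums <- rowSums(tr[, -1])
  expect_lt(max(abs(sums - 1)), 1e-9)
  expect_gt(min(as.matrix(tr[, -1])), -1e-12)
  expect_error(relax(segs, c(0.5, rep(0, 6))), "probability")
})

test_that("eigenvalues of valid generators have non-positive real parts", {
  qs <- list(build_q(scheme_full(), macro_rates_wt(), 10),
             build_q(scheme_full(), macro_rates_wt(), 0.3),
             build_q(scheme_gating(), sc_rates("E153A"), 0))
  for (q in qs) {
    sd_ <- spectral_decomposition(q)
    expect_lte(max(Re(sd_$values)), 1e-10)
    expect_false(sd_$defective)
  }
})

test_that("relaxation agrees with Monte-Carlo occupancy within 3 SE", {
  set.seed(7)
  q <- build_q(scheme_gating(), sc_rates("WT"), 0)
  p0 <- c(1, 0, 0, 0, 0)  # start in A2R
  probes <- c(0.05, 0.2, 1, 5, 25)
  n <- 1e5
  counts <- gabakin:::ctmc_occupancy_cpp(unclass(q), p0, probes, n)
  tr <- relax(list(list(q = q, duration = 26, times = probes)), p0)
  for (i in seq_along(probes)) {
    row <- tr[abs(tr$time - probes[i]) < 1e-9, -1]
    for (j in 1:5) {
      phat <- counts[i, j] / n
      se <- sqrt(max(phat * (1 - phat), 1e-8) / n)
      expect_lt(abs(phat - as.numeric(row[j])), 3 * se + 1e-4)
    }
  }
})

test_that("scheme and rate configurations round-trip through YAML", {
  d <- withr::local_tempdir()
  f1 <- file.path(d, "scheme.yaml"); f2 <- file.path(d, "rates.yaml")
  write_scheme_config(scheme_gating(), f1)
  sch <- read_scheme_config(f1)
  expect_equal(sch$states, scheme_gating()$states)
  expect_equal(sch$open_states, "A2O")
  expect_equal(sch$edges$rate, scheme_gating()$edges$rate)

  write_rates_config(sc_rates("E153K"), f2)
  r <- read_rates_config(f2)
  expect_equal(as.numeric(r), as.numeric(sc_rates("E153K")))
  expect_equal(attr(r, "genotype"), "E153K")

  # packaged fixtures load and match the built-in sets
  pk <- system.file("extdata", "rates_gating_wt.yaml", package = "gabakin")
  expect_equal(as.numeric(read_rates_config(pk)), as.numeric(sc_rates("WT")))
  pk2 <- system.file("extdata", "scheme_gating_5state.yaml", package = "gabakin")
  expect_equal(read_scheme_config(pk2)$states, scheme_gating()$states)
})
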