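test_that("effective cut-off combines analog and digital filters", {
  expect_equal(effective_cutoff(10, 10), 5)
  expect_equal(effective_cutoff(10, 1e12), 10, tolerance = 1e-10)
  expect_equal(effective_cutoff(10, 3.75), 2.727, tolerance = 1e-3)
  expect_error(effective_cutoff(-1, 5), "positive")
})

test_that("trajectory sampling is seeded, exponential and truncation-aware", {
  q <- build_q(two_state_scheme(), rate_set(c(a = 1, b = 1)), 0)
  p1 <- sample_trajectory(q, "S", n_transitions = 500, seed = 11)
  p2 <- sample_trajectory(q, "S", n_transitions = 500, seed = 11)
  expect_identical(p1, p2)

  # sojourn means: both states have unit rate -> mean 1 within 3 SE
  p <- sample_trajectory(q, "S", n_transitions = 1e5, seed = 12)
  expect_lt(abs(mean(p$sojourn_ms) - 1), 3 / sqrt(1e5))

  # per-state sojourns are exponential with rate -Q[i,i] (KS at alpha 0.01)
  q2 <- build_q(two_state_scheme(), rate_set(c(a = 2.5, b = 0.4)), 0)
  p <- sample_trajectory(q2, "S", n_transitions = 2e4, seed = 13)
  for (st in c("S", "O")) {
    x <- p$sojourn_ms[p$state == st]
    x <- x[seq_len(min(length(x), 1e4))]
    ks <- suppressWarnings(stats::ks.test(x, "pexp", -q2[st, st]))
    expect_gt(ks$p.value, 0.01)
  }

  # absorbing state flags truncation
  qa <- structure(matrix(c(-1, 1, 0, 0), 2, 2, byrow = TRUE,
                         dimnames = list(c("S", "O"), c("S", "O"))),
                  class = c("q_matrix", "matrix"))
  pa <- sample_trajectory(qa, "S", n_transitions = 100, duration = 50, seed = 1)
  expect_true(attr(pa, "truncated"))
  expect_error(sample_trajectory(q, "S"), "stopping rule")
})

test_that("long-run open-class time fraction matches equilibrium", {
  set.seed(21)
  q <- build_q(scheme_gating(), sc_rates("WT"), 0)
  p <- sample_trajectory(q, equilibrium(q), n_transitions = 2e5)
  tf <- sum(p$sojourn_ms[p$state == "A2O"]) / sum(p$sojourn_ms)
  # SE via batch means over 20 contiguous batches
  batch <- rep(seq_len(20), each = nrow(p) / 20)[seq_len(nrow(p))]
  bt <- tapply(p$sojourn_ms * (p$state == "A2O"), batch, sum) /
    tapply(p$sojourn_ms, batch, sum)
  se <- sd(bt) / sqrt(length(bt))
  expect_lt(abs(tf - equilibrium(q)[["A2O"]]), 3 * se)
})

test_that("class aggregation merges sojourns and conserves time", {
  path <- data.frame(state = c("A2R", "A2F", "A2D", "A2F", "A2O", "A2F"),
                     sojourn_ms = c(1, 2, 3, 4, 5, 6))
  ev <- aggregate_classes(path, scheme_gating())
  expect_equal(ev$class, c(0L, 1L, 0L))
  expect_equal(ev$duration_ms, c(10, 5, 6))
  expect_equal(sum(ev$duration_ms), sum(path$sojourn_ms))

  # alternating path passes through unchanged
  path2 <- data.frame(state = c("A2O", "A2F", "A2O", "A2F"),
                      sojourn_ms = c(1.5, 0.2, 2.5, 0.1))
  ev2 <- aggregate_classes(path2, scheme_gating())
  expect_equal(ev2$duration_ms, path2$sojourn_ms)

  # infinite-resolution mean open time = 1/alpha2 (open class exits via alpha2)
  set.seed(22)
  q <- build_q(scheme_gating(), sc_rates("WT"), 0)
  p <- sample_trajectory(q, equilibrium(q), n_transitions = 1e5)
  ev3 <- aggregate_classes(p, scheme_gating())
  opens <- ev3$duration_ms[ev3$class == 1]
  expect_lt(abs(mean(opens) - 1 / 1.49), 3 * sd(opens) / sqrt(length(opens)))
})

test_that("resolution imposition: identity, hand case, idempotence, conservation", {
  ev <- event_list(c(1L, 0L, 1L), c(1.0, 0.02, 1.0))
  expect_identical(impose_resolution(ev, 0), ev)

  r <- impose_resolution(ev, 0.07)
  expect_equal(r$class, 1L)
  expect_equal(r$duration_ms, 2.02)
  expect_equal(attr(r, "resolution"), 0.07)

  set.seed(23)
  q <- build_q(scheme_gating(), sc_rates("WT"), 0)
  p <- sample_trajectory(q, equilibrium(q), n_transitions = 2e4)
  raw <- aggregate_classes(p, scheme_gating())
  res <- impose_resolution(raw, 0.07)
  # all durations at or above the dead time, strict alternation
  expect_gte(min(res$duration_ms), 0.07)
  expect_true(all(diff(res$class) != 0))
  # idempotence at the same dead time
  expect_equal(impose_resolution(res, 0.07)$duration_ms, res$duration_ms)
  # duration conservation from the first resolved event
  first <- which(raw$duration_ms >= 0.07)[1]
  expect_equal(sum(res$duration_ms),
               sum(raw$duration_ms[first:nrow(raw)]), tolerance = 1e-12)

  short <- event_list(c(1L, 0L, 1L), c(0.01, 0.02, 0.03))
  expect_error(impose_resolution(short, 0.07), "no event")
})

test_that("synthetic study generation is deterministic and truth-faithful", {
  spec0 <- synthetic_study_spec(genotypes = "WT", cells_per_genotype = 1,
                                clusters_per_cell = 2,
                                events_per_cluster = 300,
                                jitter_sd = 0, seed = 5)
  st <- generate_study(spec0)
  # zero jitter: per-cell truth equals the genotype rates exactly
  expect_equal(as.numeric(st$truth[1, names(sc_rates("WT"))]),
               as.numeric(sc_rates("WT")))
  st2 <- generate_study(spec0)
  expect_identical(st$events, st2$events)
  expect_equal(length(st$events), 1)
  ev <- st$events[[1]]
  expect_equal(length(unique(ev$cluster_id)), 2)
  expect_equal(attr(ev, "resolution"), 0.07)

  # jitter perturbs rates reproducibly
  specj <- synthetic_study_spec(genotypes = "WT", cells_per_genotype = 2,
                                clusters_per_cell = 1,
                                events_per_cluster = 100,
                                jitter_sd = 0.1, seed = 6)
  stj <- generate_study(specj)
  expect_false(any(as.numeric(stj$truth[1, names(sc_rates("WT"))]) ==
                   as.numeric(sc_rates("WT"))))
})

test_that("synthetic wild-type study reproduces the measured cluster P_open", {
  spec <- synthetic_study_spec(genotypes = "WT", cells_per_genotype = 1,
                               clusters_per_cell = 6,
                               events_per_cluster = 2500,
                               jitter_sd = 0, seed = 31)
  st <- generate_study(spec)
  cs <- cluster_popen(st$events[[1]])
  expect_equal(cs$p_open, 0.77, tolerance = 0.05)
})

test_that("event-list CSV round-trips bit-exactly", {
  set.seed(29)
  ev <- event_list(rep(c(1L, 0L), 50), rexp(100) + 0.07,
                   cluster_id = rep(1:2, each = 50), resolution = 0.07)
  f <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, f)
  back <- read_events(f)
  expect_identical(back$duration_ms, ev$duration_ms)
  expect_identical(back$class, ev$class)
  expect_identical(back$cluster_id, ev$cluster_id)
  expect_equal(attr(back, "resolution"), 0.07)
})
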