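# Independent oracles used across the suite; kept free of the package's own
# computational paths wherever the test is a dual-route check.

# Detailed-balance equilibrium for tree-topology schemes: occupancy relative
# to a root state is the product of forward/backward rate ratios along the
# unique connecting path (BFS over the edge table).
tree_equilibrium_oracle <- function(scheme, rates, conc = 0) {
  states <- scheme$states
  e <- scheme$edges
  rate_of <- function(from, to) {
    i <- which(e$from == from & e$to == to)
    sum(e$factor[i] * unname(rates[e$rate[i]]) * ifelse(e$conc_dep[i], conc, 1))
  }
  w <- setNames(rep(NA_real_, length(states)), states)
  w[states[1]] <- 1
  frontier <- states[1]
  while (length(frontier)) {
    nxt <- character(0)
    for (s in frontier) {
      nb <- unique(e$to[e$from == s])
      for (t in nb) {
        if (!is.na(w[t])) next
        fwd <- rate_of(s, t); bwd <- rate_of(t, s)
        w[t] <- if (bwd > 0) w[s] * fwd / bwd else 0
        nxt <- c(nxt, t)
      }
    }
    frontier <- nxt
  }
  w / sum(w)
}

# minimal two-state open/shut scheme: shut S <-> open O with opening rate
# `b` (rate name "b"), closing rate `a`
two_state_scheme <- function() {
  kinetic_scheme(c("S", "O"), "O", rbind(
    data.frame(from = "S", to = "O", rate = "b", conc_dep = FALSE, factor = 1),
    data.frame(from = "O", to = "S", rate = "a", conc_dep = FALSE, factor = 1)))
}

# binding-only scheme where the bound state is treated as conducting
# (dose-response closed form: EC50 of the peak equals k_off/k_on)
binding_scheme <- function() {
  kinetic_scheme(c("R", "AR"), "AR", rbind(
    data.frame(from = "R", to = "AR", rate = "k_on", conc_dep = TRUE, factor = 1),
    data.frame(from = "AR", to = "R", rate = "k_off", conc_dep = FALSE, factor = 1)))
}

# Direct ideal (tau_d = 0) aggregated-Markov likelihood of an alternating
# event sequence: phi * prod G_class(t_i) * 1 with G_open(t) = expm(Qaa t) Qaf,
# computed entirely through eigen decompositions here (independent of the
# package's missed-event code path).
ideal_loglik_oracle <- function(events, scheme, rates) {
  q <- unclass(build_q(scheme, rates, 0))
  ia <- match(scheme$open_states, scheme$states)
  is <- setdiff(seq_along(scheme$states), ia)
  expm_block <- function(m, t) {
    e <- eigen(m)
    Re(e$vectors %*% diag(exp(e$values * t), nrow(m)) %*% solve(e$vectors))
  }
  p <- equilibrium(build_q(scheme, rates, 0))
  phi_a <- p[is] %*% q[is, ia, drop = FALSE]; phi_a <- phi_a / sum(phi_a)
  phi_f <- p[ia] %*% q[ia, is, drop = FALSE]; phi_f <- phi_f / sum(phi_f)
  ll <- 0
  for (cl in split(seq_len(nrow(events)), events$cluster_id)) {
    v <- if (events$class[cl[1]] == 1) phi_a else phi_f
    for (i in cl) {
      g <- if (events$class[i] == 1)
        expm_block(q[ia, ia, drop = FALSE], events$duration_ms[i]) %*%
          q[ia, is, drop = FALSE]
      else
        expm_block(q[is, is, drop = FALSE], events$duration_ms[i]) %*%
          q[is, ia, drop = FALSE]
      v <- v %*% g
      sc <- sum(v)
      ll <- ll + log(sc)
      v <- v / sc
    }
  }
  ll
}

# printed single-channel shut-time mixtures (fractions, time constants in ms)
# used as generating truth in recovery tests
shut_mixture_published <- function(genotype) {
  switch(genotype,
    WT    = list(p = c(0.67, 0.27, 0.05, 0.005), tau = c(0.03, 0.22, 1.35, 27.14)),
    E153K = list(p = c(0.57, 0.32, 0.08, 0.003), tau = c(0.04, 0.29, 1.48, 14.33)),
    E153A = list(p = c(0.52, 0.32, 0.14, 0.027), tau = c(0.05, 0.26, 1.28, 20.62)))
}

sample_mixture <- function(n, mix) {
  p <- mix$p / sum(mix$p)
  comp <- sample.int(length(p), n, replace = TRUE, prob = p)
  rexp(n, rate = 1 / mix$tau[comp])
}

# apparent events from a gating model (aggregated + dead-time imposed)
simulate_apparent_events <- function(rates, n_events, tau_d,
                                     scheme = scheme_gating()) {
  q <- build_q(scheme, rates, 0)
  ev <- gabakin:::sample_events(q, scheme$open_states, n_events, tau_d,
                                equilibrium(q))
  event_list(ev$class, ev$duration_ms, resolution = tau_d)
}

# quadrature + analytic-tail integral of an apparent density (moment 0 or 1)
integrate_apparent <- function(model, cls, moment = 0) {
  side <- model[[cls]]
  phi <- if (cls == "open") model$phi_open else model$phi_shut
  tau <- model$tau_d
  tt <- seq(tau, tau + side$span, length.out = 20001)
  f <- apparent_density(model, cls, tt)
  w <- if (moment == 0) rep(1, length(tt)) else tt^moment
  total <- sum(diff(tt) * (head(f * w, -1) + tail(f * w, -1)) / 2)
  one <- rep(1, ncol(side$m_end))
  for (i in seq_along(side$roots)) {
    s <- side$roots[i]
    ci <- side$areas[, , i]
    if (length(ci) == 1) ci <- matrix(ci)
    a <- as.numeric(phi %*% ci %*% side$m_end %*% one)
    u0 <- side$span
    total <- total + if (moment == 0) a * exp(s * u0) / (-s) else
      a * exp(s * u0) * ((u0 + tau) / (-s) + 1 / s^2)
  }
  total
}
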