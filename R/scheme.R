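#' Kinetic gating schemes for ligand-gated ion channels
#'
#' A `kinetic_scheme` is the state graph of an aggregated Markov gating model:
#' an ordered set of state labels, the subset of conducting (open) states, and
#' a table of directed edges carrying rate names, concentration dependence
#' flags and statistical factors. Every transition must be reversible (the
#' reverse edge must exist) and the graph connected; the open class must be a
#' non-empty strict subset of the states.
#'
#' @param states character vector of state labels (ordered; fixes the Q-matrix
#'   row/column order).
#' @param open_states character vector, subset of `states`, flagged conducting.
#' @param edges data frame with columns `from`, `to`, `rate` (rate-constant
#'   name), `conc_dep` (logical; multiply by agonist concentration) and
#'   `factor` (positive statistical factor).
#' @return An object of class `kinetic_scheme`.
#' @seealso [scheme_full()], [scheme_gating()], [build_q()]
#' @export
kinetic_scheme <- function(states, open_states, edges) {
  stopifnot(is.character(states), length(states) >= 1, !anyDuplicated(states))
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  req <- c("from", "to", "rate", "conc_dep", "factor")
  if (!all(req %in% names(edges)))
    stop("edges must have columns: ", paste(req, collapse = ", "))
  if (!all(edges$from %in% states) || !all(edges$to %in% states))
    stop("edge endpoints must be scheme states")
  if (any(edges$factor <= 0)) stop("statistical factors must be positive")
  if (length(open_states) == 0 || !all(open_states %in% states) ||
      length(open_states) >= length(states))
    stop("open class must be a non-empty strict subset of the states")
  # reversibility: every edge's reverse must exist
  key <- paste(edges$from, edges$to)
  rev_key <- paste(edges$to, edges$from)
  if (!all(rev_key %in% key))
    stop("missing reverse edges for: ",
         paste(key[!(rev_key %in% key)], collapse = "; "))
  # connectivity of the undirected graph
  comp <- graph_components(states, edges)
  if (length(unique(comp)) > 1)
    stop("scheme graph is not connected")
  structure(list(states = states, open_states = open_states, edges = edges),
            class = "kinetic_scheme")
}

# undirected connected-component labels from an edge table (or a Q matrix)
graph_components <- function(states, edges = NULL, q = NULL) {
  k <- length(states)
  adj <- matrix(FALSE, k, k, dimnames = list(states, states))
  if (!is.null(edges))
    for (i in seq_len(nrow(edges)))
      adj[edges$from[i], edges$to[i]] <- adj[edges$to[i], edges$from[i]] <- TRUE
  if (!is.null(q)) adj <- (abs(q) > 0) | (abs(t(q)) > 0)
  comp <- rep(NA_integer_, k)
  cur <- 0L
  for (s in seq_len(k)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier)) {
      nb <- which(apply(adj[frontier, , drop = FALSE], 2, any) & is.na(comp))
      comp[nb] <- cur
      frontier <- nb
    }
  }
  comp
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("Kinetic scheme:", length(x$states), "states (",
      paste(x$states, collapse = " "), ")\n")
  cat("  open class:", paste(x$open_states, collapse = " "), "\n")
  cat("  ", nrow(x$edges), "directed edges,",
      sum(x$edges$conc_dep), "concentration-dependent\n")
  invisible(x)
}

#' Canonical activation scheme of the alpha1-beta2-gamma2 GABA-A receptor
#'
#' Seven states: resting `R`, mono- and bi-liganded resting `A1R`, `A2R`, the
#' bi-liganded flipped (pre-open) state `A2F`, the open state `A2O`, and two
#' desensitized states `A2D` (fast, d2/r2) and `A2Dp` (slow, d2'/r2'), both
#' branching from the flipped state. Binding steps `R -> A1R -> A2R` depend on
#' agonist concentration through `k_on`; unbinding through `k_off`.
#'
#' Statistical factors for the two identical binding sites follow the per-site
#' convention by default: association `2*k_on*c` then `k_on*c`, dissociation
#' `2*k_off` then `k_off`. Set `binding_factors = c(1, 1, 1, 1)` to interpret
#' the printed rates as already containing the site multiplicity.
#'
#' @param binding_factors numeric length 4: factors for `R->A1R`, `A1R->A2R`,
#'   `A2R->A1R`, `A1R->R`.
#' @return A [kinetic_scheme()] with 7 states.
#' @export
scheme_full <- function(binding_factors = c(2, 1, 2, 1)) {
  stopifnot(length(binding_factors) == 4, all(binding_factors > 0))
  e <- rbind(
    data.frame(from = "R",    to = "A1R",  rate = "k_on",  conc_dep = TRUE,  factor = binding_factors[1]),
    data.frame(from = "A1R",  to = "A2R",  rate = "k_on",  conc_dep = TRUE,  factor = binding_factors[2]),
    data.frame(from = "A2R",  to = "A1R",  rate = "k_off", conc_dep = FALSE, factor = binding_factors[3]),
    data.frame(from = "A1R",  to = "R",    rate = "k_off", conc_dep = FALSE, factor = binding_factors[4]),
    data.frame(from = "A2R",  to = "A2F",  rate = "delta", conc_dep = FALSE, factor = 1),
    data.frame(from = "A2F",  to = "A2R",  rate = "gamma", conc_dep = FALSE, factor = 1),
    data.frame(from = "A2F",  to = "A2O",  rate = "beta",  conc_dep = FALSE, factor = 1),
    data.frame(from = "A2O",  to = "A2F",  rate = "alpha", conc_dep = FALSE, factor = 1),
    data.frame(from = "A2F",  to = "A2D",  rate = "d2",    conc_dep = FALSE, factor = 1),
    data.frame(from = "A2D",  to = "A2F",  rate = "r2",    conc_dep = FALSE, factor = 1),
    data.frame(from = "A2F",  to = "A2Dp", rate = "d2p",   conc_dep = FALSE, factor = 1),
    data.frame(from = "A2Dp", to = "A2F",  rate = "r2p",   conc_dep = FALSE, factor = 1)
  )
  kinetic_scheme(c("R", "A1R", "A2R", "A2F", "A2O", "A2D", "A2Dp"),
                 "A2O", e)
}

#' Steady-state gating scheme (binding steps omitted)
#'
#' Five states for analysis of single-channel clusters recorded at a
#' saturating agonist concentration, where the receptor is assumed fully
#' bound: `A2R <-> A2F <-> A2O` with desensitized branches `A2D` and `A2Dp`
#' off the flipped state. Rates: `delta`/`gamma` (flip/unflip), `beta2`/`alpha2`
#' (open/close), `d2`/`r2` and `d2p`/`r2p` (desensitize/resensitize).
#'
#' @return A [kinetic_scheme()] with 5 states, open class `A2O`.
#' @export
scheme_gating <- function() {
  e <- rbind(
    data.frame(from = "A2R",  to = "A2F",  rate = "delta",  conc_dep = FALSE, factor = 1),
    data.frame(from = "A2F",  to = "A2R",  rate = "gamma",  conc_dep = FALSE, factor = 1),
    data.frame(from = "A2F",  to = "A2O",  rate = "beta2",  conc_dep = FALSE, factor = 1),
    data.frame(from = "A2O",  to = "A2F",  rate = "alpha2", conc_dep = FALSE, factor = 1),
    data.frame(from = "A2F",  to = "A2D",  rate = "d2",     conc_dep = FALSE, factor = 1),
    data.frame(from = "A2D",  to = "A2F",  rate = "r2",     conc_dep = FALSE, factor = 1),
    data.frame(from = "A2F",  to = "A2Dp", rate = "d2p",    conc_dep = FALSE, factor = 1),
    data.frame(from = "A2Dp", to = "A2F",  rate = "r2p",    conc_dep = FALSE, factor = 1)
  )
  kinetic_scheme(c("A2R", "A2F", "A2O", "A2D", "A2Dp"), "A2O", e)
}

#' Named sets of transition rate constants
#'
#' A `rate_set` maps rate-constant names to values (1/ms for unimolecular
#' rates, 1/(mM*ms) for association rates) and carries a genotype label.
#'
#' @param values named numeric vector of strictly positive, finite rates.
#' @param genotype label, e.g. `"WT"`, `"E153K"`, `"E153A"` or `"custom"`.
#' @return An object of class `rate_set` (named numeric with attributes).
#' @export
rate_set <- function(values, genotype = "custom") {
  stopifnot(is.numeric(values), !is.null(names(values)), all(nzchar(names(values))))
  if (any(!is.finite(values)) || any(values <= 0))
    stop("all rates must be strictly positive and finite")
  structure(values, genotype = genotype, class = c("rate_set", "numeric"))
}

#' @export
print.rate_set <- function(x, ...) {
  cat("Rate set (", attr(x, "genotype"), "):\n", sep = "")
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Fitted macroscopic model rates for the wild-type receptor
#'
#' The published rate constants of the seven-state activation model tuned to
#' reproduce wild-type macroscopic responses to 500 ms saturating GABA pulses:
#' `k_on` = 10 /(mM*ms), `k_off` = 0.9, `delta` = 5, `gamma` = 4, `beta` = 25,
#' `alpha` = 1.2, `d2` = 20, `r2` = 0.15, `d2p` = 1.0, `r2p` = 0.005 (1/ms).
#'
#' @return A [rate_set()] for [scheme_full()].
#' @export
macro_rates_wt <- function() {
  rate_set(c(k_on = 10, k_off = 0.9, delta = 5, gamma = 4, beta = 25,
             alpha = 1.2, d2 = 20, r2 = 0.15, d2p = 1.0, r2p = 0.005),
           genotype = "WT")
}

#' Fitted single-channel gating rates per genotype
#'
#' Missed-event-corrected maximum-likelihood estimates of the eight gating
#' rates of the five-state steady-state scheme, per genotype (1/ms):
#' wild type, the charge-reversal mutant E153K and the hydrophobic mutant
#' E153A of the beta2 subunit loop B residue.
#'
#' @param genotype `"WT"`, `"E153K"` or `"E153A"`.
#' @return A [rate_set()] for [scheme_gating()].
#' @export
sc_rates <- function(genotype = c("WT", "E153K", "E153A")) {
  genotype <- match.arg(genotype)
  v <- switch(genotype,
    WT    = c(delta = 6.14, gamma = 7.76, beta2 = 27.25, alpha2 = 1.49,
              d2 = 1.17, r2 = 0.87, d2p = 0.12, r2p = 0.09),
    E153K = c(delta = 5.34, gamma = 5.17, beta2 = 17.27, alpha2 = 1.41,
              d2 = 1.09, r2 = 0.99, d2p = 0.07, r2p = 0.10),
    E153A = c(delta = 5.60, gamma = 6.16, beta2 = 14.14, alpha2 = 1.51,
              d2 = 2.05, r2 = 0.86, d2p = 0.30, r2p = 0.06))
  rate_set(v, genotype = genotype)
}

#' Assemble the infinitesimal generator (Q-matrix)
#'
#' Off-diagonal entry (from, to) is `factor * rate * conc` for
#' concentration-dependent edges and `factor * rate` otherwise; the diagonal
#' closes each row to zero. Units 1/ms throughout (`conc` in mM).
#'
#' @param scheme a [kinetic_scheme()].
#' @param rates a [rate_set()] containing every rate name the scheme uses.
#' @param conc agonist concentration in mM (>= 0).
#' @return A `q_matrix`: numeric matrix with attributes `conc` and `scheme`.
#' @export
build_q <- function(scheme, rates, conc = 0) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (!is.numeric(conc) || length(conc) != 1 || is.na(conc) || conc < 0)
    stop("concentration must be a single non-negative number (mM)")
  missing_rates <- setdiff(unique(scheme$edges$rate), names(rates))
  if (length(missing_rates))
    stop("rate set lacks: ", paste(missing_rates, collapse = ", "))
  k <- length(scheme$states)
  q <- matrix(0, k, k, dimnames = list(scheme$states, scheme$states))
  for (i in seq_len(nrow(scheme$edges))) {
    e <- scheme$edges[i, ]
    v <- e$factor * unname(rates[[e$rate]]) * if (e$conc_dep) conc else 1
    q[e$from, e$to] <- q[e$from, e$to] + v
  }
  diag(q) <- -rowSums(q)
  structure(q, conc = conc, scheme = scheme, class = c("q_matrix", "matrix"))
}

q_open_idx <- function(q) {
  scheme <- attr(q, "scheme")
  match(scheme$open_states, scheme$states)
}

#' Equilibrium state occupancy
#'
#' Solves `p Q = 0`, `sum(p) = 1` by least squares on the augmented system.
#' If the chain is reducible at the Q-matrix's concentration (e.g. binding
#' edges vanish at zero agonist), the computation can be restricted to the
#' connected component containing `component_of`; otherwise reducibility is an
#' error naming the disconnected states.
#'
#' @param q a `q_matrix` from [build_q()].
#' @param component_of optional state label; restrict to its component and
#'   report zero occupancy elsewhere.
#' @return Named occupancy vector (non-negative, sums to 1).
#' @export
equilibrium <- function(q, component_of = NULL) {
  states <- rownames(q)
  comp <- graph_components(states, q = unclass(q))
  if (length(unique(comp)) > 1) {
    if (is.null(component_of))
      stop("Q is reducible; disconnected states: ",
           paste(states[comp != comp[1]], collapse = ", "),
           " (pass component_of= to restrict)")
    keep <- comp == comp[match(component_of, states)]
  } else keep <- rep(TRUE, length(states))
  qq <- unclass(q)[keep, keep, drop = FALSE]
  k <- nrow(qq)
  a <- rbind(t(qq), rep(1, k))
  b <- c(rep(0, k), 1)
  p_sub <- qr.solve(a, b)
  p <- setNames(numeric(length(states)), states)
  p[keep] <- p_sub
  p[p < 0 & p > -1e-12] <- 0
  p
}

#' Spectral decomposition of a generator
#'
#' Eigen-decomposition of Q giving eigenvalues, spectral projection matrices
#' `A_k` with `expm(Q t) = sum_k A_k exp(lambda_k t)`, and the equilibrium
#' occupancy (null left eigenvector). Used by [relax()]; the projections can
#' be inspected to read relaxation time constants and amplitudes.
#'
#' @param q a `q_matrix`.
#' @return List with `values` (eigenvalues), `projections` (list of matrices),
#'   `equilibrium`, and `defective` (TRUE when eigenvalue spacing is too small
#'   for a reliable spectral path).
#' @export
spectral_decomposition <- function(q) {
  e <- eigen(unclass(q))
  lam <- e$values
  scale <- max(abs(lam), 1e-12)
  gap <- min(abs(outer(lam, lam, "-")[upper.tri(diag(length(lam)))]), Inf)
  defective <- is.finite(gap) && gap < 1e-8 * scale
  proj <- NULL
  if (!defective) {
    vi <- solve(e$vectors)
    proj <- lapply(seq_along(lam), function(k)
      Re(e$vectors[, k] %o% vi[k, ]) + 1i * Im(e$vectors[, k] %o% vi[k, ]))
  }
  peq <- tryCatch(equilibrium(q), error = function(e) NULL)
  list(values = lam, projections = proj, equilibrium = peq,
       defective = defective)
}

# matrix exponential by scaling-and-squaring on the spectral path being
# unavailable; Pade order 6 is ample for generator matrices at these rates
expm_q <- function(m, t) {
  a <- m * t
  nrm <- max(rowSums(abs(a)))
  j <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 1L)
  a <- a / 2^j
  # Pade(6,6)
  c6 <- c(1, 1 / 2, 5 / 44, 1 / 66, 1 / 792, 1 / 15840, 1 / 665280)
  k <- nrow(a)
  a2 <- a %*% a
  u <- c6[2] * diag(k) + c6[4] * a2 + c6[6] * a2 %*% a2
  u <- a %*% u
  v <- c6[1] * diag(k) + c6[3] * a2 + c6[5] * a2 %*% a2 + c6[7] * a2 %*% a2 %*% a2
  f <- solve(v - u, v + u)
  for (i in seq_len(j)) f <- f %*% f
  f
}

#' Relax state occupancies through a sequence of concentration epochs
#'
#' Piecewise solution of `dp/dt = p Q` across segments (Q-matrix, duration),
#' as under an agonist pulse protocol. Within each segment the solution is
#' the spectral expansion `p(t) = sum_k (p0 A_k) exp(lambda_k t)`; a
#' scaled-and-squared matrix exponential is used instead when the spectrum is
#' near-degenerate (relative eigenvalue spacing below 1e-8).
#'
#' @param segments list of segments, each `list(q = <q_matrix>, duration =
#'   <ms>, times = <optional local sample times>)`; `times` defaults to
#'   `seq(0, duration, by = dt)`.
#' @param p0 initial occupancy vector (sums to 1).
#' @param dt default sampling step in ms.
#' @return data frame: `time` (ms, global) plus one occupancy column per state.
#' @export
relax <- function(segments, p0, dt = 0.05) {
  stopifnot(length(segments) >= 1)
  if (abs(sum(p0) - 1) > 1e-8 || any(p0 < -1e-12))
    stop("p0 must be a probability vector over the states")
  states <- rownames(segments[[1]]$q)
  p0 <- as.numeric(p0)
  out <- list()
  t_base <- 0
  for (seg in segments) {
    q <- seg$q
    if (!is.numeric(seg$duration) || seg$duration <= 0)
      stop("segment durations must be positive")
    times <- if (!is.null(seg$times)) seg$times else seq(0, seg$duration, by = dt)
    if (max(times) < seg$duration) times <- c(times, seg$duration)
    occ <- relax_segment(q, p0, times)
    out[[length(out) + 1]] <- cbind(time = t_base + times, occ)
    p0 <- occ[nrow(occ), ]
    t_base <- t_base + seg$duration
  }
  res <- as.data.frame(do.call(rbind, out))
  names(res) <- c("time", states)
  # drop duplicated boundary points between segments
  res[!duplicated(res$time), , drop = FALSE]
}

relax_segment <- function(q, p0, times) {
  k <- nrow(q)
  sd_ <- spectral_decomposition(q)
  if (!sd_$defective) {
    e <- eigen(unclass(q))
    vi <- solve(e$vectors)
    a <- as.vector(p0 %*% e$vectors)
    occ <- vapply(seq_len(k), function(j)
      Re(colSums(a * exp(outer(e$values, times)) * vi[, j])),
      numeric(length(times)))
    if (length(times) == 1) occ <- matrix(occ, nrow = 1)
  } else {
    occ <- matrix(NA_real_, length(times), k)
    ord <- order(times)
    p <- p0
    t_prev <- 0
    for (i in ord) {
      p <- as.vector(p %*% expm_q(unclass(q), times[i] - t_prev))
      occ[i, ] <- p
      t_prev <- times[i]
    }
  }
  occ
}

#' Open-class probability from a relaxation trajectory
#'
#' @param traj data frame from [relax()].
#' @param scheme the scheme the trajectory was computed for.
#' @return numeric vector of summed open-state occupancies.
#' @export
open_probability <- function(traj, scheme) {
  unname(rowSums(traj[, scheme$open_states, drop = FALSE]))
}

# ---- structured-text (YAML) configuration ----------------------------------

#' Read or write scheme and rate-set configurations
#'
#' Schemes and rate sets serialize to a YAML document with blocks `states`,
#' `open_states`, `edges` (from/to/rate/conc_dep/factor) and, for rate files,
#' `rates` (name: value, 1/ms or 1/(mM*ms)) and `genotype`. The packaged
#' configurations under `inst/extdata` carry the published macroscopic and
#' single-channel rate sets.
#'
#' @param path file path.
#' @return `read_scheme_config`: a [kinetic_scheme()]; `read_rates_config`:
#'   a [rate_set()].
#' @name scheme_io
NULL

#' @rdname scheme_io
#' @param scheme a [kinetic_scheme()] to serialize.
#' @export
write_scheme_config <- function(scheme, path) {
  yaml::write_yaml(list(
    states = as.list(scheme$states),
    open_states = as.list(scheme$open_states),
    edges = lapply(seq_len(nrow(scheme$edges)), function(i)
      as.list(scheme$edges[i, ]))), path)
  invisible(path)
}

#' @rdname scheme_io
#' @export
read_scheme_config <- function(path) {
  x <- yaml::read_yaml(path)
  edges <- do.call(rbind, lapply(x$edges, function(e)
    data.frame(from = e$from, to = e$to, rate = e$rate,
               conc_dep = isTRUE(e$conc_dep), factor = as.numeric(e$factor))))
  kinetic_scheme(unlist(x$states), unlist(x$open_states), edges)
}

#' @rdname scheme_io
#' @param rates a [rate_set()] to serialize.
#' @export
write_rates_config <- function(rates, path) {
  yaml::write_yaml(list(genotype = attr(rates, "genotype"),
                        rates = as.list(setNames(as.numeric(rates), names(rates)))),
                   path)
  invisible(path)
}

#' @rdname scheme_io
#' @export
read_rates_config <- function(path) {
  x <- yaml::read_yaml(path)
  rate_set(unlist(x$rates), genotype = x$genotype %||% "custom")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
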