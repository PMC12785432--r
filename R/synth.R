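#' Effective filter cut-off frequency
#'
#' Combined analog + digital low-pass cut-off: `1/f_c = 1/f_a + 1/f_d`.
#'
#' @param f_a analog filter cut-off (kHz).
#' @param f_d digital filter cut-off (kHz).
#' @return Effective cut-off `f_c` in kHz.
#' @export
effective_cutoff <- function(f_a, f_d) {
  if (any(f_a <= 0) || any(f_d <= 0))
    stop("filter cut-off frequencies must be positive")
  1 / (1 / f_a + 1 / f_d)
}

#' Single-channel event lists
#'
#' An event list holds alternating open/shut sojourn durations grouped into
#' clusters of channel activity, together with the recording resolution (dead
#' time) that has been imposed on it. Class coding follows the packaged CSV
#' dialect: `0` = shut, `1` = open.
#'
#' @param cls integer vector (0 shut, 1 open).
#' @param duration_ms numeric sojourn durations (ms).
#' @param cluster_id integer cluster labels (events of a cluster contiguous).
#' @param resolution imposed dead time in ms (0 = ideal).
#' @param provenance optional list (scheme, rates, seed) for synthetic data.
#' @return Object of class `event_list`: data frame with columns
#'   `cluster_id`, `event_index`, `class`, `duration_ms`.
#' @export
event_list <- function(cls, duration_ms, cluster_id = 1L, resolution = 0,
                       provenance = NULL) {
  n <- length(cls)
  stopifnot(length(duration_ms) == n, all(cls %in% c(0L, 1L)))
  if (length(cluster_id) == 1) cluster_id <- rep(cluster_id, n)
  stopifnot(length(cluster_id) == n)
  if (is.unsorted(cluster_id)) stop("cluster events must be contiguous")
  df <- data.frame(cluster_id = as.integer(cluster_id),
                   event_index = stats::ave(seq_len(n), cluster_id,
                                            FUN = seq_along),
                   class = as.integer(cls), duration_ms = duration_ms)
  for (cl in split(df$class, df$cluster_id))
    if (length(cl) > 1 && any(diff(cl) == 0))
      stop("classes must strictly alternate within a cluster")
  if (any(duration_ms < resolution - 1e-12))
    stop("durations below the stated resolution")
  structure(df, resolution = resolution, provenance = provenance,
            class = c("event_list", "data.frame"))
}

#' @export
print.event_list <- function(x, ...) {
  cat("Event list:", nrow(x), "events in", length(unique(x$cluster_id)),
      "cluster(s); resolution", attr(x, "resolution"), "ms\n")
  invisible(x)
}

#' Sample a continuous-time Markov chain trajectory
#'
#' Exact (Gillespie) sampling of the gating chain: sojourns are exponential
#' with rate `-Q[i,i]`, successors drawn proportionally to the off-diagonal
#' rates. Randomness comes from R's RNG, so `seed` (or an enclosing
#' `set.seed()`) makes output reproducible. If an absorbing state is reached
#' before the stopping rule, the path is truncated and flagged.
#'
#' @param q a `q_matrix` from [build_q()].
#' @param p0 initial state: a state label, or an occupancy vector to draw
#'   the initial state from.
#' @param n_transitions stop after this many sojourns (ignored if `duration`
#'   given and reached first).
#' @param duration stop when total time reaches this many ms.
#' @param seed optional integer seed.
#' @return data frame `state`, `sojourn_ms` with attribute `truncated`.
#' @export
sample_trajectory <- function(q, p0, n_transitions = 0L, duration = Inf,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_transitions <= 0 && !is.finite(duration))
    stop("give a stopping rule: n_transitions or duration")
  states <- rownames(q)
  if (is.character(p0)) {
    start <- match(p0, states)
    if (is.na(start)) stop("unknown start state: ", p0)
  } else {
    stopifnot(length(p0) == length(states), abs(sum(p0) - 1) < 1e-8)
    start <- sample.int(length(states), 1, prob = pmax(p0, 0))
  }
  res <- ctmc_sample_cpp(unclass(q), start, as.integer(n_transitions), duration)
  structure(data.frame(state = states[res$state], sojourn_ms = res$duration),
            truncated = res$truncated)
}

#' Aggregate a state path into open/shut events
#'
#' Collapses a trajectory onto the two conductance classes, merging
#' consecutive sojourns of the same class by summing durations, as dwell-time
#' analysis sees them. Total duration is conserved exactly.
#'
#' @param path data frame from [sample_trajectory()].
#' @param open_states character vector of conducting state labels, or a
#'   [kinetic_scheme()].
#' @return An [event_list()] (one cluster, ideal resolution).
#' @export
aggregate_classes <- function(path, open_states) {
  if (inherits(open_states, "kinetic_scheme")) open_states <- open_states$open_states
  if (nrow(path) == 0) stop("empty path")
  cls <- as.integer(path$state %in% open_states)
  run <- cumsum(c(1L, diff(cls) != 0))
  event_list(cls[!duplicated(run)],
             as.numeric(tapply(path$sojourn_ms, run, sum)))
}

#' Impose a finite recording resolution (dead time)
#'
#' Standard forward-concatenation convention: scanning forward from the first
#' event at least as long as the dead time, any shorter event is unresolvable
#' and its duration -- together with the following event, which then has the
#' same class as the current resolved event -- is absorbed into the preceding
#' resolved event. Output durations all exceed the dead time, classes
#' alternate, and total duration from the first resolved event is conserved.
#' The operation is idempotent at a fixed dead time.
#'
#' @param events an [event_list()].
#' @param tau_d dead time in ms (>= 0; 0 is the identity).
#' @return An [event_list()] with `resolution = tau_d`.
#' @export
impose_resolution <- function(events, tau_d) {
  if (tau_d < 0) stop("dead time must be non-negative")
  if (tau_d == 0) return(events)
  out <- lapply(split(seq_len(nrow(events)), events$cluster_id), function(ix) {
    r <- impose_resolution_cpp(events$class[ix], events$duration_ms[ix], tau_d)
    if (length(r$class) == 0)
      stop("no event reaches the dead time (", tau_d, " ms) in cluster ",
           events$cluster_id[ix[1]])
    data.frame(cluster_id = events$cluster_id[ix[1]], class = r$class,
               duration_ms = r$duration)
  })
  res <- do.call(rbind, out)
  event_list(res$class, res$duration_ms, res$cluster_id, resolution = tau_d,
             provenance = attr(events, "provenance"))
}

# sample apparent (aggregated + resolution-imposed) events from a gating
# model, continuing the chain in chunks until n_events are available
sample_events <- function(q, open_states, n_events, tau_d, p0,
                          chunk = NULL) {
  states <- rownames(q)
  if (is.null(chunk)) chunk <- max(2000L, as.integer(n_events * 8L))
  cls_all <- integer(0); dur_all <- numeric(0)
  if (is.character(p0)) start <- match(p0, states)
  else start <- sample.int(length(states), 1, prob = pmax(p0, 0))
  repeat {
    res <- ctmc_sample_cpp(unclass(q), start, chunk, Inf)
    cls <- as.integer(states[res$state] %in% open_states)
    run <- cumsum(c(1L, diff(cls) != 0))
    agg_cls <- cls[!duplicated(run)]
    agg_dur <- as.numeric(tapply(res$duration, run, sum))
    cls_all <- c(cls_all, agg_cls); dur_all <- c(dur_all, agg_dur)
    r <- impose_resolution_cpp(cls_all, dur_all, tau_d)
    if (length(r$class) >= n_events + 1) break
    start <- res$state[length(res$state)]
  }
  keep <- seq_len(n_events)
  event_list(r$class[keep], r$duration[keep], resolution = tau_d)
}

#' Specification of a synthetic single-channel study
#'
#' Describes the synthetic counterpart of a cell-attached cluster-recording
#' study at saturating agonist: several cells per genotype, several clusters
#' per cell, apparent events per cluster, lognormal between-cell scatter on
#' every gating rate, and the recording dead time. The defaults emulate the
#' study conditions: 5 cells per genotype, a 0.07 ms dead time (the midpoint
#' of the 40-90 us instrumental resolution range) and 10% between-cell rate
#' jitter.
#'
#' @param genotypes character vector of genotype labels understood by
#'   [sc_rates()], or a named list of [rate_set()]s.
#' @param cells_per_genotype,clusters_per_cell,events_per_cluster counts.
#' @param jitter_sd lognormal sdlog applied per cell to every rate (0 = none).
#' @param dead_time recording resolution in ms.
#' @param entry one of `"non_slow_desensitized"` (cluster entry occupancy is
#'   the equilibrium conditioned on not being in the long-lived desensitized
#'   state, whose sojourns delimit clusters) or `"equilibrium"`.
#' @param seed master seed; the whole study regenerates identically from it.
#' @return Object of class `study_spec`.
#' @export
synthetic_study_spec <- function(genotypes = c("WT", "E153K", "E153A"),
                                 cells_per_genotype = 5,
                                 clusters_per_cell = 8,
                                 events_per_cluster = 1500,
                                 jitter_sd = 0.1, dead_time = 0.07,
                                 entry = c("non_slow_desensitized",
                                           "equilibrium"),
                                 seed = 1L) {
  entry <- match.arg(entry)
  if (is.character(genotypes))
    genotypes <- setNames(lapply(genotypes, sc_rates), genotypes)
  stopifnot(cells_per_genotype >= 0, clusters_per_cell > 0,
            events_per_cluster > 0, jitter_sd >= 0, dead_time >= 0)
  structure(list(genotypes = genotypes,
                 cells_per_genotype = cells_per_genotype,
                 clusters_per_cell = clusters_per_cell,
                 events_per_cluster = events_per_cluster,
                 jitter_sd = jitter_sd, dead_time = dead_time,
                 entry = entry, seed = as.integer(seed)),
            class = "study_spec")
}

#' Generate a synthetic single-channel study
#'
#' For each cell, the genotype's gating rates are perturbed by seeded
#' lognormal jitter (between-cell biological scatter); each cluster is then
#' simulated from the cluster-entry occupancy, aggregated into open/shut
#' events and truncated to the recording resolution. Ground-truth per-cell
#' rates are returned alongside for recovery tests.
#'
#' @param spec a [synthetic_study_spec()].
#' @param scheme gating scheme shared by all genotypes
#'   (default [scheme_gating()]).
#' @return List with `events` (named list, one [event_list()] per cell with
#'   clusters as separate ids), `truth` (data frame of per-cell true rates)
#'   and `spec`.
#' @export
generate_study <- function(spec, scheme = scheme_gating()) {
  set.seed(spec$seed)
  events <- list()
  truth <- list()
  for (g in names(spec$genotypes)) {
    base <- spec$genotypes[[g]]
    for (cell in seq_len(spec$cells_per_genotype)) {
      jit <- if (spec$jitter_sd > 0)
        rlnorm(length(base), meanlog = 0, sdlog = spec$jitter_sd) else
        rep(1, length(base))
      rates_cell <- rate_set(setNames(as.numeric(base) * jit, names(base)),
                             genotype = g)
      q <- build_q(scheme, rates_cell, 0)
      p_entry <- cluster_entry_occupancy(q, scheme, spec$entry)
      cl <- lapply(seq_len(spec$clusters_per_cell), function(i) {
        ev <- sample_events(q, scheme$open_states, spec$events_per_cluster,
                            spec$dead_time, p_entry)
        data.frame(cluster_id = i, class = ev$class,
                   duration_ms = ev$duration_ms)
      })
      cl <- do.call(rbind, cl)
      id <- paste0(g, "_cell", cell)
      events[[id]] <- event_list(cl$class, cl$duration_ms, cl$cluster_id,
                                 resolution = spec$dead_time,
                                 provenance = list(genotype = g, cell = cell,
                                                   seed = spec$seed))
      truth[[id]] <- data.frame(genotype = g, cell = cell,
                                t(as.numeric(rates_cell)))
      names(truth[[id]])[-(1:2)] <- names(base)
    }
  }
  list(events = events, truth = do.call(rbind, c(truth, make.row.names = FALSE)),
       spec = spec)
}

cluster_entry_occupancy <- function(q, scheme, entry) {
  p <- equilibrium(q)
  if (entry == "non_slow_desensitized" && "A2Dp" %in% names(p)) {
    p["A2Dp"] <- 0
    p <- p / sum(p)
  }
  p
}

#' Read and write event-list CSV files
#'
#' The packaged dialect: a `# resolution_ms=<x>` comment line, a header row
#' `cluster_id,event_index,class,duration_ms` (class 0 = shut, 1 = open), one
#' event per row, UTF-8. Durations are written with full precision so that a
#' write/read cycle is bit-exact.
#'
#' @param events an [event_list()].
#' @param path file path.
#' @return `read_events`: an [event_list()]; `write_events`: `path`,
#'   invisibly.
#' @name event_io
#' @export
write_events <- function(events, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# resolution_ms=%.17g", attr(events, "resolution")), con)
  writeLines("cluster_id,event_index,class,duration_ms", con)
  writeLines(sprintf("%d,%d,%d,%.17g", events$cluster_id, events$event_index,
                     events$class, events$duration_ms), con)
  invisible(path)
}

#' @rdname event_io
#' @export
read_events <- function(path) {
  first <- readLines(path, n = 1)
  res <- 0
  if (startsWith(first, "# resolution_ms="))
    res <- as.numeric(sub("# resolution_ms=", "", first))
  df <- read.csv(path, comment.char = "#")
  event_list(df$class, df$duration_ms, df$cluster_id, resolution = res)
}
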