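#' Extract a dwell-time sample from an event list
#'
#' Pulls the durations of one conductance class, carrying the event list's
#' resolution as the left-truncation bound for likelihood fitting.
#'
#' @param events an [event_list()].
#' @param cls `"open"` or `"shut"`.
#' @return Object of class `dwell_sample`: list with `durations` (ms),
#'   `class`, `tau_d` (left-truncation bound, ms), `source` (cluster ids).
#' @export
dwell_sample <- function(events, cls = c("open", "shut")) {
  cls <- match.arg(cls)
  code <- if (cls == "open") 1L else 0L
  sel <- events$class == code
  if (!any(sel)) stop("no ", cls, " events in the list")
  structure(list(durations = events$duration_ms[sel], class = cls,
                 tau_d = attr(events, "resolution") %||% 0,
                 source = events$cluster_id[sel]),
            class = "dwell_sample")
}

#' Logarithmically binned dwell-time histogram
#'
#' Standard display for dwell-time distributions: log10-spaced bins with a
#' square-root ordinate. The returned object also carries the transform
#' needed to overlay a fitted mixture density on the same axes (counts scale:
#' `n * bin_width_log10 * ln(10) * t * f(t)`).
#'
#' @param sample a [dwell_sample()] or numeric vector of durations (ms).
#' @param bins_per_decade number of bins per decade of duration.
#' @return Object of class `dwell_histogram`: data frame `left`, `right`,
#'   `mid` (geometric), `count`, `sqrt_count` with attributes `n` and
#'   `bins_per_decade`.
#' @export
log_histogram <- function(sample, bins_per_decade = 10) {
  t <- if (inherits(sample, "dwell_sample")) sample$durations else sample
  if (length(t) == 0) stop("empty dwell-time sample")
  if (any(t <= 0)) stop("durations must be positive")
  lo <- floor(log10(min(t)) * bins_per_decade) / bins_per_decade
  hi <- ceiling(log10(max(t)) * bins_per_decade) / bins_per_decade
  if (hi <= lo) hi <- lo + 1 / bins_per_decade
  edges <- 10^seq(lo, hi, by = 1 / bins_per_decade)
  ct <- tabulate(findInterval(t, edges, rightmost.closed = TRUE),
                 nbins = length(edges) - 1)
  structure(data.frame(left = edges[-length(edges)], right = edges[-1],
                       mid = sqrt(edges[-length(edges)] * edges[-1]),
                       count = ct, sqrt_count = sqrt(ct)),
            n = length(t), bins_per_decade = bins_per_decade,
            class = c("dwell_histogram", "data.frame"))
}

#' Overlay curve of an exponential mixture on a log histogram
#'
#' @param m an [exp_mixture] (see [fit_exp_mixture()]).
#' @param hist a [log_histogram()] result (supplies n and bin width), or a
#'   list with `n` and `bins_per_decade`.
#' @param t evaluation times (ms).
#' @return data frame `t`, `count_scale` for plotting over the histogram.
#' @export
mixture_overlay <- function(m, hist, t) {
  n <- attr(hist, "n") %||% hist$n
  bpd <- attr(hist, "bins_per_decade") %||% hist$bins_per_decade
  f <- exp_mixture_density(m, t)
  data.frame(t = t, count_scale = n * (1 / bpd) * log(10) * t * f)
}

exp_mixture_density <- function(m, t, tau_d = m$tau_d %||% 0) {
  z <- sum(m$components$p * exp(-tau_d / m$components$tau))
  rowSums(vapply(seq_len(nrow(m$components)), function(j)
    m$components$p[j] / m$components$tau[j] * exp(-t / m$components$tau[j]),
    numeric(length(t)))) / z
}

#' Left-truncated exponential-mixture maximum likelihood fit
#'
#' Maximum likelihood for the dwell-time density
#' `f(t) = sum_i P_i (1/tau_i) exp(-t/tau_i) / sum_i P_i exp(-tau_d/tau_i)`,
#' `t >= tau_d`. Because exponentials are memoryless, the shifted data
#' `t - tau_d` follow an untruncated mixture whose weights are the truncated
#' reweighting of `P`; that mixture is fitted by EM (initial time constants
#' log-spaced over the sample's quantile range, seeded multiplicative
#' restarts), and the best EM solution is polished by quasi-Newton ascent
#' (BFGS over log time constants and softmax weights) — EM alone can crawl
#' for thousands of iterations on overlapping components. The untruncated
#' `P_i` are recovered afterwards. Components are returned sorted by
#' ascending time constant. If two fitted time constants collapse within 1%
#' the fit is repeated at `k - 1` with a warning.
#'
#' @param sample a [dwell_sample()] or numeric vector of durations (ms).
#' @param k number of exponential components (>= 1).
#' @param tau_d left-truncation bound in ms (defaults to the sample's).
#' @param restarts number of EM restarts (first from the log-spaced
#'   initialization, the rest jittered).
#' @param max_iter,tol per-restart EM stopping rule (log-likelihood change);
#'   final convergence comes from the polish step.
#' @return Object of class `exp_mixture`: list with `components` (data frame
#'   `p`, `tau` ascending), `logLik`, `k`, `tau_d`, `n`, `warnings`.
#' @export
fit_exp_mixture <- function(sample, k, tau_d = NULL, restarts = 5,
                            max_iter = 300, tol = 1e-8) {
  t_raw <- if (inherits(sample, "dwell_sample")) sample$durations else sample
  if (is.null(tau_d))
    tau_d <- if (inherits(sample, "dwell_sample")) sample$tau_d else 0
  stopifnot(k >= 1, tau_d >= 0)
  if (any(t_raw < tau_d - 1e-12))
    stop("durations below the truncation bound tau_d")
  n <- length(t_raw)
  if (n < 50 * k)
    warning("fewer than 50 observations per component (n = ", n, ", k = ", k, ")")
  x <- pmax(t_raw - tau_d, .Machine$double.eps)
  warnings <- character()

  em_once <- function(tau0, w0) {
    tau <- tau0; w <- w0
    ll_prev <- -Inf
    lg <- matrix(0, n, k)
    for (it in seq_len(max_iter)) {
      for (j in seq_len(k))
        lg[, j] <- log(w[j]) - log(tau[j]) - x / tau[j]
      mx <- lg[, 1]
      if (k > 1) for (j in 2:k) mx <- pmax(mx, lg[, j])
      pz <- exp(lg - mx)          # column-major recycling subtracts per row
      sz <- rowSums(pz)
      ll <- sum(mx + log(sz))
      g <- pz / sz
      w <- colMeans(g)
      tau <- pmax(colSums(g * x) / pmax(colSums(g), 1e-300), 1e-9)
      if (is.finite(ll) && ll - ll_prev < tol && it > 5) break
      ll_prev <- ll
    }
    list(tau = tau, w = w, ll = ll)
  }

  # direct negative log-likelihood over (log tau, softmax weights)
  direct_nll <- function(th) {
    tau <- exp(th[seq_len(k)])
    w <- if (k == 1) 1 else {
      a <- c(0, th[(k + 1):(2 * k - 1)])
      exp(a - max(a)) / sum(exp(a - max(a)))
    }
    lg <- matrix(0, n, k)
    for (j in seq_len(k)) lg[, j] <- log(w[j]) - th[j] - x / tau[j]
    mx <- lg[, 1]
    if (k > 1) for (j in 2:k) mx <- pmax(mx, lg[, j])
    -sum(mx + log(rowSums(exp(lg - mx))))
  }

  run_k <- function(k) {
    # initial time constants log-spaced across the sample's quantile range:
    # dwell-time components span decades, and linearly spaced quantiles
    # leave rare slow components without a nearby seed
    qr <- pmax(quantile(x, probs = c(0.05, 0.999), names = FALSE), 1e-9)
    qs <- if (k == 1) mean(x) else
      exp(seq(log(qr[1]), log(qr[2]), length.out = k))
    best <- NULL
    for (r in seq_len(restarts)) {
      tau0 <- if (r == 1) qs else qs * exp(rnorm(k, 0, 0.5))
      fit <- em_once(sort(tau0), rep(1 / k, k))
      if (is.null(best) || fit$ll > best$ll) best <- fit
    }
    # quasi-Newton polish from the best EM point
    th0 <- if (k == 1) log(best$tau) else
      c(log(best$tau), log(pmax(best$w[-1], 1e-12) / max(best$w[1], 1e-12)))
    opt <- tryCatch(
      optim(th0, direct_nll, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(opt) && -opt$value >= best$ll) {
      tau <- exp(opt$par[seq_len(k)])
      w <- if (k == 1) 1 else {
        a <- c(0, opt$par[(k + 1):(2 * k - 1)])
        exp(a - max(a)) / sum(exp(a - max(a)))
      }
      best <- list(tau = tau, w = w, ll = -opt$value)
    }
    best
  }

  best <- run_k(k)
  ord <- order(best$tau)
  tau <- best$tau[ord]; w <- best$w[ord]
  if (k > 1 && any(tau[-1] / tau[-k] < 1.01)) {
    warnings <- c(warnings, "degenerate components; refitted at k-1")
    warning("two time constants collapsed within 1%; refitting with k = ", k - 1)
    k <- k - 1
    best <- run_k(k)
    ord <- order(best$tau)
    tau <- best$tau[ord]; w <- best$w[ord]
  }
  # untruncated mixture fractions from the truncated weights
  p <- w * exp(tau_d / tau)
  p <- p / sum(p)
  structure(list(components = data.frame(p = p, tau = tau),
                 logLik = best$ll, k = k, tau_d = tau_d, n = n,
                 warnings = warnings),
            class = "exp_mixture")
}

#' @export
print.exp_mixture <- function(x, ...) {
  cat("Exponential mixture (k = ", x$k, ", tau_d = ", x$tau_d, " ms, n = ",
      x$n, "):\n", sep = "")
  comp <- x$components
  comp$p <- signif(comp$p, 4); comp$tau <- signif(comp$tau, 4)
  print(comp, row.names = FALSE)
  cat("logLik:", format(x$logLik), "\n")
  invisible(x)
}

#' Weighted mean dwell time of an exponential mixture
#'
#' `sum(P_i tau_i)` with the fractions renormalized, the mean dwell time
#' across all weighted components.
#'
#' @param m an `exp_mixture`, or a list/data frame with `p` and `tau`.
#' @return Mean dwell time in ms.
#' @export
mixture_mean <- function(m) {
  comp <- if (inherits(m, "exp_mixture")) m$components else as.data.frame(m)
  p <- comp$p / sum(comp$p)
  sum(p * comp$tau)
}

#' Cluster open probability and mean dwell times
#'
#' Per cluster, `P_open` is total open time over total time (exactly the
#' open-time fraction); cluster values are averaged unweighted across
#' clusters, as when each cluster is one observation within a cell. Clusters
#' with no open events get `P_open = 0` and are flagged.
#'
#' @param events an [event_list()].
#' @return Object of class `cluster_stats`: list with `per_cluster` (data
#'   frame `cluster_id`, `p_open`, `mean_open`, `mean_shut`, `n_open`,
#'   `n_shut`), unweighted means `p_open`, `mean_open`, `mean_shut`, and
#'   `flagged` (ids of open-free clusters).
#' @export
cluster_popen <- function(events) {
  per <- lapply(split(seq_len(nrow(events)), events$cluster_id), function(ix) {
    cls <- events$class[ix]; dur <- events$duration_ms[ix]
    open <- dur[cls == 1L]; shut <- dur[cls == 0L]
    data.frame(cluster_id = events$cluster_id[ix[1]],
               p_open = if (length(open)) sum(open) / sum(dur) else 0,
               mean_open = if (length(open)) mean(open) else NA_real_,
               mean_shut = if (length(shut)) mean(shut) else NA_real_,
               n_open = length(open), n_shut = length(shut))
  })
  per <- do.call(rbind, c(per, make.row.names = FALSE))
  flagged <- per$cluster_id[per$n_open == 0]
  if (length(flagged))
    warning("cluster(s) without open events: ", paste(flagged, collapse = ", "))
  structure(list(per_cluster = per,
                 p_open = mean(per$p_open),
                 mean_open = mean(per$mean_open, na.rm = TRUE),
                 mean_shut = mean(per$mean_shut, na.rm = TRUE),
                 flagged = flagged),
            class = "cluster_stats")
}

#' @export
print.cluster_stats <- function(x, ...) {
  cat("Cluster stats over", nrow(x$per_cluster), "clusters: P_open",
      signif(x$p_open, 3), "; mean open", signif(x$mean_open, 3),
      "ms; mean shut", signif(x$mean_shut, 3), "ms\n")
  invisible(x)
}

#' Genotype summary of per-cell parameters
#'
#' Mean, standard error and n per parameter and genotype, the layout of a
#' per-cell summary table. A single cell yields SE 0 with `n = 1` (flagged by
#' the n column itself). Missing values are dropped per parameter, so n can
#' differ between parameters of the same genotype.
#'
#' @param cells data frame with a `genotype` column, optionally a `cell`
#'   column, and numeric parameter columns (one row per cell).
#' @return data frame: `genotype`, `parameter`, `mean`, `se`, `n`.
#' @export
summarize_cells <- function(cells) {
  stopifnot("genotype" %in% names(cells))
  params <- names(cells)[vapply(cells, is.numeric, logical(1))]
  params <- setdiff(params, c("cell"))
  out <- list()
  for (g in unique(cells$genotype)) {
    sub <- cells[cells$genotype == g, , drop = FALSE]
    for (p in params) {
      v <- sub[[p]][!is.na(sub[[p]])]
      n <- length(v)
      if (n == 0) next
      out[[length(out) + 1]] <- data.frame(
        genotype = g, parameter = p, mean = mean(v),
        se = if (n > 1) sd(v) / sqrt(n) else 0, n = n)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
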