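#' Z-score outlier detection
#'
#' Flags values whose absolute z-score (relative to the group mean and SD)
#' exceeds a threshold. Flagged values are excluded from downstream group
#' statistics with a message.
#'
#' @param values numeric vector (n >= 3 for a meaningful SD).
#' @param threshold |z| cut-off (default 3).
#' @return Logical mask, `TRUE` for outliers.
#' @export
detect_outliers <- function(values, threshold = 3) {
  if (length(values) < 3) return(rep(FALSE, length(values)))
  s <- sd(values)
  if (!is.finite(s) || s == 0) return(rep(FALSE, length(values)))
  abs(values - mean(values)) / s > threshold
}

# Dunn's rank-based pairwise z tests after Kruskal-Wallis, with the standard
# tie correction, and the Holm-Sidak step-down adjustment.
dunn_test <- function(values, groups) {
  n <- length(values)
  rk <- rank(values)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  gl <- split(rk, groups)
  rbar <- vapply(gl, mean, numeric(1))
  ng <- vapply(gl, length, numeric(1))
  nm <- names(gl)
  pairs <- utils::combn(nm, 2, simplify = FALSE)
  out <- lapply(pairs, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ng[i] + 1 / ng[j]))
    z <- (rbar[i] - rbar[j]) / se
    data.frame(group1 = i, group2 = j, z = z,
               p = 2 * pnorm(-abs(z)))
  })
  res <- do.call(rbind, out)
  res$p_adj <- holm_sidak(res$p)
  res
}

# Holm-Sidak step-down adjustment: ordered p_i adjusted as
# 1 - (1 - p_(i))^(m - i + 1), enforced monotone non-decreasing.
holm_sidak <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

#' Compare a kinetic parameter across genotype groups
#'
#' The study's statistics decision rule: Shapiro-Wilk normality per group
#' and Levene's test for equality of variances; if every group is normal and
#' variances are homogeneous, one-way ANOVA with Tukey HSD post hoc,
#' otherwise the Kruskal-Wallis H-test with Dunn's pairwise test under
#' Holm-Sidak correction. Post-hoc results are reported only when the
#' omnibus test is significant at `alpha`. Optionally z-score outliers are
#' removed per group first.
#'
#' @param values numeric vector of per-cell parameter values.
#' @param groups group labels (>= 2 groups, >= 3 values each).
#' @param alpha significance level (default 0.05).
#' @param outlier_threshold z cut-off passed to [detect_outliers()]
#'   (`Inf` disables removal).
#' @param parameter optional parameter name carried into the result.
#' @return Object of class `group_comparison`: list with `parameter`,
#'   `groups` (per-group n, mean, se), `normality_p`, `levene_p`, `test`
#'   (`"anova"` or `"kruskal"`), `omnibus_p`, `posthoc` (data frame or NULL),
#'   `significant` (named logical per non-reference pair at `alpha`),
#'   `excluded` (outlier indices).
#' @export
compare_groups <- function(values, groups, alpha = 0.05,
                           outlier_threshold = 3, parameter = NA_character_) {
  groups <- as.character(groups)
  keep <- complete.cases(values, groups)
  values <- values[keep]; groups <- groups[keep]
  excluded <- integer(0)
  if (is.finite(outlier_threshold)) {
    mask <- unlist(lapply(split(seq_along(values), groups), function(ix)
      ix[detect_outliers(values[ix], outlier_threshold)]))
    if (length(mask)) {
      message("excluding ", length(mask), " outlier value(s) by |z| > ",
              outlier_threshold)
      excluded <- sort(unname(mask))
      groups <- groups[-excluded]; values <- values[-excluded]
    }
  }
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 3)) {
    warning("need >= 2 groups with >= 3 values each; comparison skipped")
    return(structure(list(parameter = parameter, groups = NULL,
                          normality_p = NULL, levene_p = NA_real_,
                          test = NA_character_, omnibus_p = NA_real_,
                          posthoc = NULL, significant = NULL,
                          excluded = excluded),
                     class = "group_comparison"))
  }
  gsum <- do.call(rbind, lapply(names(tab), function(g) {
    v <- values[groups == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               se = sd(v) / sqrt(length(v)))
  }))
  norm_p <- vapply(split(values, groups), function(v) {
    if (length(unique(v)) < 3) return(0)  # degenerate: not normal
    shapiro.test(v)$p.value
  }, numeric(1))
  lev_p <- tryCatch(
    car::leveneTest(values ~ factor(groups))[1, "Pr(>F)"],
    error = function(e) NA_real_)
  parametric <- all(norm_p > alpha) && isTRUE(lev_p > alpha)
  if (parametric) {
    fit <- aov(values ~ factor(groups))
    omnibus_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    posthoc <- NULL
    if (is.finite(omnibus_p) && omnibus_p < alpha) {
      tk <- TukeyHSD(fit)[[1]]
      posthoc <- data.frame(
        group1 = sub("-.*", "", rownames(tk)),
        group2 = sub(".*-", "", rownames(tk)),
        diff = tk[, "diff"], p_adj = tk[, "p adj"], row.names = NULL)
    }
    test <- "anova"
  } else {
    kw <- kruskal.test(values, factor(groups))
    omnibus_p <- kw$p.value
    posthoc <- NULL
    if (is.finite(omnibus_p) && omnibus_p < alpha)
      posthoc <- dunn_test(values, groups)
    test <- "kruskal"
  }
  significant <- NULL
  if (!is.null(posthoc)) {
    significant <- setNames(posthoc$p_adj < alpha,
                            paste(posthoc$group1, posthoc$group2, sep = " vs "))
  }
  structure(list(parameter = parameter, groups = gsum, normality_p = norm_p,
                 levene_p = lev_p, test = test, omnibus_p = omnibus_p,
                 posthoc = posthoc, significant = significant,
                 excluded = excluded),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison", if (!is.na(x$parameter)) paste0("(", x$parameter, ")"),
      ": ", x$test, " omnibus p = ", signif(x$omnibus_p, 3),
      "\n", sep = "")
  if (!is.null(x$posthoc)) {
    ph <- x$posthoc
    ph$p_adj <- signif(ph$p_adj, 3)
    print(ph, row.names = FALSE)
  }
  invisible(x)
}

#' Configuration of an end-to-end in-silico study
#'
#' Bundles everything [run_study()] needs: the macroscopic model and pulse
#' protocol, the synthetic single-channel study specification, dwell-time
#' analysis settings, statistics settings, and a master seed. Identical
#' config plus seed reproduces identical outputs.
#'
#' @param synth a [synthetic_study_spec()].
#' @param macro_rates a [rate_set()] for the macroscopic model (or NULL to
#'   skip the macroscopic stage).
#' @param macro_scheme scheme for the macroscopic stage.
#' @param protocol a [pulse_protocol()].
#' @param shut_k,open_k exponential-mixture component counts.
#' @param fit_rates run the missed-event ML stage per cell (slowest stage).
#' @param alpha significance level for group statistics.
#' @param outlier_threshold z cut-off for outlier exclusion.
#' @param seed master seed (propagated to the synthesis spec).
#' @return Object of class `study_config`.
#' @export
study_config <- function(synth = synthetic_study_spec(),
                         macro_rates = macro_rates_wt(),
                         macro_scheme = scheme_full(),
                         protocol = saturating_pulse(),
                         shut_k = 4, open_k = 1, fit_rates = FALSE,
                         alpha = 0.05, outlier_threshold = 3, seed = 1L) {
  synth$seed <- as.integer(seed)
  structure(list(synth = synth, macro_rates = macro_rates,
                 macro_scheme = macro_scheme, protocol = protocol,
                 shut_k = shut_k, open_k = open_k, fit_rates = fit_rates,
                 alpha = alpha, outlier_threshold = outlier_threshold,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Run the full in-silico study pipeline
#'
#' Executes the study stages in order -- macroscopic descriptor extraction,
#' single-channel synthesis, dwell-time and cluster analysis per cell,
#' optional missed-event ML rate estimation per cell, and group statistics --
#' and returns (optionally writes) the result tables plus a manifest with
#' the seed and stage status. A failing stage is recorded in the manifest
#' and downstream stages that depend on it are skipped; the partial bundle
#' is still returned.
#'
#' @param config a [study_config()].
#' @param out_dir optional directory; when given, tables are written as CSV
#'   and the manifest as JSON.
#' @return List with `macro` (descriptor table), `cells` (per-cell dwell
#'   summary), `mixtures` (per-cell fitted components), `fits` (per-cell
#'   fitted rates, if enabled), `comparisons` (per-parameter
#'   [compare_groups()] results), `summary` (genotype summary table),
#'   `manifest`.
#' @export
run_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  manifest <- list(seed = config$seed, created = format(Sys.time()),
                   package_version = as.character(utils::packageVersion("gabakin")),
                   stages = list())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      warning("stage '", name, "' failed: ", conditionMessage(e))
      structure(list(message = conditionMessage(e)), class = "stage_error")
    })
    manifest$stages[[name]] <<- if (inherits(res, "stage_error"))
      list(status = "error", message = res$message) else list(status = "ok")
    res
  }

  macro <- NULL
  if (!is.null(config$macro_rates))
    macro <- stage("macro", macro_kinetics(config$macro_scheme,
                                           config$macro_rates,
                                           config$protocol))

  study <- stage("synthesis", generate_study(config$synth))

  cells <- NULL; mixtures <- NULL
  if (!inherits(study, "stage_error") && length(study$events) > 0) {
    per_cell <- stage("dwell", {
      rows <- list(); mixes <- list()
      for (id in names(study$events)) {
        ev <- study$events[[id]]
        prov <- attr(ev, "provenance")
        cs <- cluster_popen(ev)
        sh <- fit_exp_mixture(dwell_sample(ev, "shut"), k = config$shut_k)
        op <- fit_exp_mixture(dwell_sample(ev, "open"), k = config$open_k)
        rows[[id]] <- data.frame(genotype = prov$genotype, cell = prov$cell,
                                 p_open = cs$p_open, mean_open = cs$mean_open,
                                 mean_shut_weighted = mixture_mean(sh),
                                 open_tau = mixture_mean(op))
        mixes[[id]] <- cbind(genotype = prov$genotype, cell = prov$cell,
                             class = rep(c("shut", "open"),
                                         c(nrow(sh$components), nrow(op$components))),
                             rbind(sh$components, op$components))
      }
      list(rows = do.call(rbind, c(rows, make.row.names = FALSE)),
           mixes = do.call(rbind, c(mixes, make.row.names = FALSE)))
    })
    if (!inherits(per_cell, "stage_error")) {
      cells <- per_cell$rows
      mixtures <- per_cell$mixes
    }
  }

  fits <- NULL
  if (isTRUE(config$fit_rates) && !inherits(study, "stage_error") &&
      length(study$events) > 0) {
    fits <- stage("hjc_fit", {
      rows <- lapply(names(study$events), function(id) {
        ev <- study$events[[id]]
        prov <- attr(ev, "provenance")
        fit <- fit_gating_rates(ev)
        cbind(data.frame(genotype = prov$genotype, cell = prov$cell,
                         logLik = fit$logLik, converged = fit$converged),
              as.data.frame(t(as.numeric(fit$rates)),
                            col.names = names(fit$rates)))
      })
      do.call(rbind, c(rows, make.row.names = FALSE))
    })
    if (inherits(fits, "stage_error")) fits <- NULL
  }

  comparisons <- NULL; summary_tab <- NULL
  if (!is.null(cells) && nrow(cells) > 0) {
    stats_res <- stage("statistics", {
      params <- setdiff(names(cells), c("genotype", "cell"))
      comp <- lapply(params, function(p)
        compare_groups(cells[[p]], cells$genotype, alpha = config$alpha,
                       outlier_threshold = config$outlier_threshold,
                       parameter = p))
      names(comp) <- params
      list(comparisons = comp, summary = summarize_cells(cells))
    })
    if (!inherits(stats_res, "stage_error")) {
      comparisons <- stats_res$comparisons
      summary_tab <- stats_res$summary
    }
  }

  bundle <- list(macro = if (!inherits(macro, "stage_error")) macro,
                 cells = cells, mixtures = mixtures, fits = fits,
                 comparisons = comparisons, summary = summary_tab,
                 manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(bundle$macro))
      write.csv(bundle$macro, file.path(out_dir, "macro_descriptors.csv"),
                row.names = FALSE)
    if (!is.null(cells))
      write.csv(cells, file.path(out_dir, "cell_summary.csv"), row.names = FALSE)
    if (!is.null(mixtures))
      write.csv(mixtures, file.path(out_dir, "dwell_mixtures.csv"),
                row.names = FALSE)
    if (!is.null(fits))
      write.csv(fits, file.path(out_dir, "fitted_rates.csv"), row.names = FALSE)
    if (!is.null(summary_tab))
      write.csv(summary_tab, file.path(out_dir, "genotype_summary.csv"),
                row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  bundle
}
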