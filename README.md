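# gabakin

Kinetic modeling and single-channel analysis of GABA-A receptor gating in
R.

GABA-A receptors are the pentameric chloride channels mediating fast
synaptic inhibition. Their activity is well described by aggregated Markov
("Q-matrix") gating schemes: agonist binding, a pre-open "flipped"
conformation, opening/closing, and desensitized states. Working with such
models day to day means four recurring computational tasks, and `gabakin`
implements all of them for the alpha1-beta2-gamma2 receptor and its loop-B
binding-site mutants (beta2-E153K, beta2-E153A):

1. **Macroscopic simulation** — deterministic relaxation of the state
   occupancies under agonist concentration pulses, via the spectral
   expansion `p(t) = sum_k (p0 A_k) e^{lambda_k t}` of each epoch's
   generator, with extraction of the standard descriptors: 10-90% rise
   time, biexponential desensitization
   (`A_f e^{-t/tau_f} + A_s e^{-t/tau_s} + C`), fractions remaining,
   single-exponential deactivation, and four-parameter log-logistic
   EC50 fits — plus systematic single-rate perturbation scans over the
   0.05-10x multiplier grid.
2. **Stochastic single-channel synthesis** — exact CTMC sampling of gating
   trajectories, aggregation into alternating open/shut events, cluster
   structure, between-cell rate scatter, and imposition of a finite
   recording resolution (dead time).
3. **Dwell-time analysis** — log-binned histograms and left-truncated
   exponential-mixture maximum likelihood
   (`f(t) = sum_i P_i (1/tau_i) e^{-t/tau_i} / sum_i P_i e^{-tau_d/tau_i}`),
   cluster open probability, per-cell and per-genotype summaries.
4. **Missed-event-corrected rate estimation** — the exact
   Hawkes-Jalali-Colquhoun treatment of apparent dwell times at dead time
   `tau_d` (piecewise-exact survivor matrices, asymptotic roots of
   `det[sI - Q_AA - Q_AF S_FF(s) Q_FA] = 0` beyond), and maximum-likelihood
   estimation of all eight gating rates of the five-state steady-state
   scheme from resolution-limited event lists.

The published fitted rate constants for the macroscopic wild-type model
and the single-channel models of all three genotypes ship with the package
(`macro_rates_wt()`, `sc_rates()`, plus YAML configurations under
`inst/extdata/`). The methods vignette
(`vignettes/gating-kinetics.Rmd`) documents the model assumptions, the
numerical machinery and its accuracy checks, and known limitations.

## Worked example

Simulate the wild-type macroscopic response to the canonical protocol
(1 ms baseline, 500 ms pulse of 10 mM GABA, 2000 ms washout) and extract
its kinetics:

```r
library(gabakin)
desc <- macro_kinetics(scheme_full(), macro_rates_wt())
round(t(desc[1, c("peak", "rt", "tau_des_fast", "tau_des_slow",
                  "apct_des_fast", "fr500", "tau_dea")]), 3)
#> peak            0.408
#> rt              0.303
#> tau_des_fast    1.732
#> tau_des_slow   93.270
#> apct_des_fast   0.716
#> fr500           0.144
#> tau_dea       362.059
```

Peak open probability 0.41, sub-millisecond rise, a biexponential sag
dominated by the fast component, 14% of the peak current left at pulse
end, and a 362 ms deactivation — the model's rendering of the measured
wild-type response (whose mean deactivation constant is 407.68 ms). A
10-fold increase of the unbinding rate, the mechanism proposed for the
E153 mutants, accelerates deactivation to 107 ms and shifts the EC50
4.5-fold (111 -> 497 uM):

```r
scan <- rate_scan(scheme_full(), macro_rates_wt(), "k_off")
subset(scan$table, multiplier %in% c(1, 10), c(multiplier, tau_dea))
#>   multiplier  tau_dea
#>          1.0 362.0590
#>         10.0 107.2974
```

On the single-channel side, the analytic equilibrium of the five-state
gating scheme reproduces the measured cluster open probabilities, and
missed-event-corrected fitting recovers the gating rates from synthetic
event lists:

```r
equilibrium(build_q(scheme_gating(), sc_rates("WT"), 0))[["A2O"]]
#> [1] 0.7872634   # measured cluster P_open: 0.77

set.seed(1)
q  <- build_q(scheme_gating(), sc_rates("WT"), 0)
ev <- impose_resolution(
  aggregate_classes(sample_trajectory(q, equilibrium(q),
                                      n_transitions = 2e5), scheme_gating()),
  0.07)
fit <- fit_gating_rates(ev)   # ~2 min: simplex with restart polishing
fit$rates[c("beta2", "alpha2")]   # generating values 27.25, 1.49
```

The numbered scripts under `analysis/` run the full study pipeline —
macroscopic descriptors, rate scans, synthetic three-genotype
single-channel study (5 cells x 8 clusters x 1500 events each), per-cell
dwell analysis, per-cell missed-event rate fits, and the group statistics
(Shapiro-Wilk/Levene gated ANOVA-Tukey or Kruskal-Wallis-Dunn) — writing
tables under `results/`.

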