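---
title: "Kinetic modeling of GABA-A receptor gating: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic modeling of GABA-A receptor gating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gabakin)
```

## The models

`gabakin` analyzes the gating of the alpha1-beta2-gamma2 GABA-A receptor
with aggregated Markov models, at two levels.

The **activation scheme** (`scheme_full()`) has seven states:

```
R  <->  A1R  <->  A2R  <->  A2F  <->  A2O
                            |  \
                           A2D  A2D'
```

Two sequential agonist binding steps (`k_on` per site, in 1/(mM ms), and
`k_off`) lead to the doubly bound resting state `A2R`; a conformational
"flip" (`delta`/`gamma`) reaches the pre-open intermediate `A2F`, from which
the channel opens (`beta`/`alpha`) or desensitizes into a fast (`A2D`,
`d2`/`r2`) or slow (`A2D'`, `d2'`/`r2'`) desensitized state. The packaged
wild-type rate set (`macro_rates_wt()`) is the published macroscopic model
fitted to 500 ms responses at a saturating 10 mM GABA pulse.

The **steady-state gating scheme** (`scheme_gating()`) drops the binding
steps: single-channel clusters are recorded at saturating agonist where the
receptor is taken to be fully bound, so only the five bi-liganded states
remain, with opening rate `beta2` and closing rate `alpha2`. Fitted rate
sets for the wild type and the two loop-B mutants (charge reversal E153K,
hydrophobic E153A) ship as `sc_rates()`.

Two structural choices deserve comment, because the published scheme figure
fixes them only graphically:

* **Desensitization topology.** Both desensitized states branch from the
  flipped state `A2F`. This is the only attachment for which the analytic
  equilibrium open occupancy of the fitted single-channel rates reproduces
  the measured cluster open probabilities of all three genotypes
  (0.787/0.765/0.497 versus measured 0.77/0.75/0.50); attaching the slow
  desensitized state to the open state instead gives 0.395 for the wild
  type, and in the macroscopic model drives deactivation into the seconds.
  The shortest shut-time component also then matches the measured 0.03 ms.
* **Binding statistical factors.** The printed model carries one
  `k_on`/`k_off` pair for two identical binding sites. The package defaults
  to the per-site convention (`2 k_on c`, `k_on c` association;
  `2 k_off`, `k_off` dissociation), the standard choice for two equivalent
  sites; `scheme_full(binding_factors = c(1, 1, 1, 1))` interprets the
  printed rates as already containing the multiplicity. The source is
  silent on this point.

Units are fixed package-wide: milliseconds, 1/ms, mM.

## Macroscopic responses and descriptors

`simulate_pulse()` relaxes the occupancy vector through the epochs of a
concentration protocol by the spectral expansion of each epoch's Q-matrix
(`p(t) = sum_k (p0 A_k) e^{lambda_k t}`); a scaled-and-squared matrix
exponential takes over if the spectrum is nearly degenerate (relative
eigenvalue spacing below 1e-8 — never the case for the shipped schemes).
The canonical protocol `saturating_pulse()` is 1 ms of baseline (so the
simulation starts from rest), a 500 ms pulse of 10 mM agonist, and 2000 ms
of washout, sampled at 0.01 ms for the first 10 ms of each epoch and 0.1 ms
after; every descriptor changes by less than 0.1% under further refinement
(this is a tested property).

The descriptor set mirrors standard macroscopic analysis:

* `rise_time_10_90()` — first crossings of 10% and 90% of the peak on the
  rising limb, linearly interpolated. The peak itself is the global maximum
  on the sampled grid with parabolic refinement through the three
  neighboring samples.
* `fit_desensitization()` — nonnegative least squares of
  `A_f e^{-t/tau_f} + A_s e^{-t/tau_s} + C` from the peak to pulse end,
  components ordered so `tau_fast <= tau_slow`; percentages are computed
  with the offset in the denominator, `A%_f = A_f / (A_f + A_s + C)`.
* `fraction_remaining()` — `Amp(t_peak + t) / Amp_max`.
* `fit_deactivation()` — `A e^{-t/tau}` (no offset) over the first 2000 ms
  of washout, time re-zeroed at agonist removal. The window is
  configurable.
* `fit_log_logistic()` — the four-parameter log-logistic (Hill) curve
  `A = A_min + (A_max - A_min) / (1 + (EC50/c)^{n_H})`, fitted on
  log-concentration. Dose-response curves use the normalized peak response
  per concentration; whether the original analysis used peak or
  steady-state response is not stated, and peak is the whole-cell EC50
  analogue.

`rate_scan()` re-simulates the protocol with one rate scaled over the
published 21-multiplier grid (0.05-10x, `scan_multipliers()`), emitting the
full descriptor table per multiplier; the multiplier-1 row goes through the
identical code path as the unperturbed model and is bitwise identical to
it.

```{r macro, eval = FALSE}
desc <- macro_kinetics(scheme_full(), macro_rates_wt())
scan <- rate_scan(scheme_full(), macro_rates_wt(), "k_off")
```

### What the macroscopic model does and does not reproduce

With the shipped rates the simulated wild-type response gives a
deactivation time constant of about 362 ms (measured mean 407.68 ms), a
fast-desensitization percentage of about 0.65 and FR500 of about 0.14 —
all within the scatter one expects from a model fitted to a family of
responses. Two descriptors are systematically sharper in the simulation
than in the recordings: the 10-90% rise time (about 0.30 ms versus 0.51 ms
measured) and the fast desensitization time constant (about 1.7 ms versus
3.2 ms). The package simulates an instantaneous concentration step, whereas
the recordings used a piezo-driven theta-glass exchange with a 150-250 us
open-tip exchange time plus 10 kHz filtering, which broadens exactly these
sub-millisecond features; solution-exchange modeling is deliberately out of
scope. The washout decay of the model is distinctly biexponential (about
67 ms and 475 ms components), so the single-exponential deactivation fit
mixes them; this is why the k_off-scan fold-change in `tau_dea` (about
3.4-fold for a 10-fold k_off increase) understates the measured ~5-fold
mutant acceleration even though the EC50 fold-change (about 4.9) matches.

## Synthetic single-channel data

`generate_study()` is the package's stand-in for idealized cell-attached
cluster recordings at saturating agonist. Per cell, the genotype's gating
rates receive lognormal between-cell jitter (default sdlog 0.1, emulating
the scatter of per-cell fits without claiming its covariance structure);
clusters are then simulated by exact CTMC (Gillespie) sampling from a
cluster-entry occupancy, aggregated into alternating open/shut class
events, and truncated to the recording resolution. Defaults are the study
conditions: 5 cells per genotype, 8 clusters per cell, 1500 apparent events
per cluster, dead time 0.07 ms — the midpoint of the 40-90 us instrumental
resolution range.

* **Cluster entry.** Real clusters are delimited by long-lived desensitized
  periods, so entry occupancy defaults to the equilibrium conditioned on
  *not* being in `A2D'`; pure equilibrium is available
  (`entry = "equilibrium"`). The original cluster-selection criterion was
  visual and is not reproducible; synthetic clusters are defined by
  construction, and cluster-length statistics should not be compared
  against recordings.
* **Resolution imposition** (`impose_resolution()`) uses the standard
  forward-concatenation convention: the record opens at the first event at
  least as long as the dead time; any shorter event is unresolvable and is
  absorbed, together with its successor, into the preceding resolved event.
  The operation conserves total duration, keeps strict alternation, and is
  idempotent at a fixed dead time (all tested).
* What the generator does **not** emulate: raw current waveforms, filter
  rise times, baseline noise, amplitude heterogeneity, multiple channels
  per patch, or idealization errors. Passing tests therefore demonstrate
  correctness of the analysis chain on data whose generating process is
  exactly the model class — not robustness to the idealization artifacts
  of real recordings.

Event lists serialize to a small CSV dialect (`write_events()` /
`read_events()`: `cluster_id, event_index, class, duration_ms`, class 0 =
shut / 1 = open, with the resolution in a header comment), written with
full precision so round-trips are bit-exact.

## Dwell-time analysis

`fit_exp_mixture()` fits left-truncated exponential mixtures by maximum
likelihood on the raw durations (histograms are display-only,
`log_histogram()` giving the conventional log-abscissa, square-root
ordinate view). The truncated density

`f(t) = sum_i P_i (1/tau_i) e^{-t/tau_i} / sum_i P_i e^{-tau_d/tau_i}`,
for `t >= tau_d`,

is handled through the memorylessness of the exponential: the shifted data
`t - tau_d` follow an untruncated mixture whose weights are the truncated
reweighting of `P`, so standard EM applies, and the untruncated fractions
are recovered afterwards. Initial time constants are log-spaced over the
sample's quantile range (dwell components span decades; linearly spaced
seeds leave rare slow components uncovered), with four multiplicatively
jittered restarts, and the best EM solution is polished by BFGS on log
time constants and softmax weights — EM alone can crawl for thousands of
iterations when components overlap, and the polish step reaches the
maximum in seconds. If two components collapse within 1% the fit is
repeated at `k - 1` with a warning. Component counts follow the published description (shut k = 4,
open k = 1) rather than an information criterion. Cluster open probability
is the open-time fraction per cluster, averaged unweighted across clusters
and then across cells (`cluster_popen()`, `summarize_cells()`), matching a
per-cell reporting layout where n can differ between parameters.

## Missed-event correction and rate estimation

The core of the package is the exact missed-event treatment of apparent
dwell times (the Hawkes-Jalali-Colquhoun theory). With the open/shut
partition `A`/`F` of the generator and dead time `tau_d`, the survivor
matrix `R_A(u)` of "e-open" periods (open periods extended by shut
excursions shorter than `tau_d`) has Laplace transform
`[sI - Q_AA - Q_AF S_FF(s) Q_FA]^{-1}` with
`S_FF(s) = int_0^tau e^{-sw} e^{Q_FF w} dw`.

* **Exact region.** Rather than transcribing the published recursive
  coefficient expressions, `R_A(u)` is obtained by integrating the
  equivalent delay integro-differential system: the convolution reduces,
  through the spectral expansion of the return kernel
  `Q_AF e^{Q_FF w} Q_FA`, to auxiliary matrix ODEs with a single lagged
  term, integrated by RK4 (250 steps per dead-time width) with
  cubic-Hermite interpolation for the lag. The delay branch switches per
  integration step, because the system has a derivative kink at `u = tau_d`
  and evaluating the wrong one-sided derivative at the kink collapses the
  quadrature order. Tables span five dead-time widths.
* **Asymptotic region.** Beyond the tabulated span,
  `R(u) = sum_i e^{s_i u} C_i` with `s_i` the real negative roots of
  `det W(s) = 0`, `W(s) = sI - Q_AA - Q_AF S_FF(s) Q_FA`, found by a dense
  sign-change scan plus bisection, and areas
  `C_i = r_i l_i' / (l_i' W'(s_i) r_i)` from the null vectors of `W(s_i)`.
  At the switch point the two representations agree to ~1e-12, and the
  apparent densities integrate to 1 within 1e-6 (both tested; observed
  normalization defect is ~1e-8). Missed-event treatments conventionally
  switch to the asymptotic form at three dead-time widths; the longer
  tabulated span costs microseconds and keeps the normalization check
  comfortably inside its bound.
* **Entry vectors.** A recorded period must first survive one dead time
  contiguously in its own class, so the steady-state class-entry vectors
  are propagated through `e^{Q_class tau_d}` and renormalized. This matters
  greatly for the shut class, whose entry state (the flipped state) exits
  within ~0.03 ms: without the factor the predicted mean apparent shut time
  is low by a factor of two. Exact start/end vectors for a defined critical
  time (CHS-style) are not implemented; the steady-state choice is an
  approximation affecting only cluster boundaries, negligible at the
  cluster lengths used here.
* **Likelihood.** `cluster_log_likelihood()` is the forward product of the
  apparent density matrices over each cluster's alternating dwell sequence
  with per-step rescaling (log-domain); the compiled inner loop makes a
  5e4-event evaluation essentially free next to the per-parameter-set
  model build.
* **Optimization.** `fit_gating_rates()` maximizes over log-rates with
  Nelder-Mead. A single simplex pass reliably stalls on this 8-dimensional
  surface, so each start is polished by re-launching the simplex from its
  own endpoint until the gain drops below 0.05 log-units; independent
  jittered starts are available on top (`restarts`). The neutral default
  initialization (`neutral_init_rates()`) orders the three shut branches
  by exit rate so the fitted branches keep their conventional labels —
  the two-state branches hanging off the flipped state are exchangeable by
  symmetry, and only this ordering convention distinguishes "flip" from
  "fast desensitized" in a fit.

### Identifiability at a saturating dead time

With a single open state, every apparent dwell starts from the same entry
state, so apparent open and shut durations are essentially independent
draws from two marginal densities, and the likelihood sees the eight rates
only through those two curves. Different rate vectors can produce nearly
identical density pairs, which makes the likelihood surface a narrow,
nearly flat manifold: on synthetic wild-type data (5e4 events, 0.07 ms
dead time) fits from the neutral start land around 8-11% below the
generating `beta2`/`alpha2` with a log-likelihood a few units *above* the
generating values — exactly the Wilks expectation for an 8-parameter fit,
and the model's marginal distributions match simulation at the 1e6-event
level. Recovered rates at this design should therefore be read with
~10-15% headroom, which is also the tolerance used in the acceptance
checks; the genotype ordering of the opening rate
(`beta2`: WT > E153K > E153A) is robust.

## Group statistics

`compare_groups()` reproduces the study's decision rule: Shapiro-Wilk per
group and a Levene variance check; if all groups pass both, one-way ANOVA
with Tukey HSD, otherwise Kruskal-Wallis with Dunn's rank test under
Holm-Sidak correction (implemented in-package with the standard tie
correction, since no installed package provides it). Post-hoc tables are
reported only when the omnibus test is significant at alpha = 0.05.
Z-score outlier screening (default threshold 3, configurable — the
original threshold is unstated) runs per group beforehand. Summaries
report mean, SE and per-parameter n.

## Problem sizes and reproducibility

All randomness flows through R's RNG; `generate_study()` and
`run_study()` regenerate bit-identical output from a master seed. The test
suite runs the heavier checks at sizes chosen to finish comfortably on one
CPU: mixture-recovery at 2e5 draws per genotype set, simulation oracles at
1e5-1e6 events, Monte-Carlo relaxation checks at 1e5 trajectories, and
rate-recovery fits at 1e4 (genotype ordering) and 5e4 (wild-type recovery)
events. The analysis scripts under `analysis/` run the same pipeline at
the study's own design (5 cells x 8 clusters x 1500 events per genotype).

## Known limitations

* Instantaneous solution exchange only; sub-millisecond onset descriptors
  are sharper than in recordings (see above).
* Tree-topology schemes only: no cyclic schemes, hence no microscopic
  reversibility constraint solver; reversibility is implicit in the tree.
* One conductance class; no sublevels, no amplitude modeling.
* Steady-state likelihood boundary vectors (no CHS start/end vectors, no
  explicit critical-time cluster segmentation).
* The between-cell jitter model is a convenience (independent lognormal
  per rate), not an inference about the real covariance of cell-to-cell
  variability.
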