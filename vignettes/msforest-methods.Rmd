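---
title: "Multistate survival forests and recursively imputed trees: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistate survival forests and recursively imputed trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msforest)
```

## The model

A multistate process `X(t)` lives on a finite state set; the package
supports acyclic progressive chains (`1 → 2 → … → N`) and the illness-death
graph (`1 → 2`, `1 → 3`, `2 → 3`). The process is characterized either by
transition probabilities `P_hj(s,t)` or transition intensities `α_hj(t)`.
Each transition carries a *clock*: `forward` (time since study origin — the
Markov convention) or `reset` (time since entry into the origin state — the
semi-Markov convention, natural when the clinically meaningful outcome is
the sojourn duration, e.g. time from intermediate diagnosis to death).

Everything is built on the **separate approach**: for each transition
`h → j` a transition-specific dataset is extracted whose risk set is every
subject who visits `h`; exits to other states and losses to follow-up are
cause-specific censorings. On each such dataset the package offers three
estimators of the conditional cumulative hazard `Â_hj(t | z)`:

* **Covariate-free baseline** — the Nelson–Aalen estimator; assembling all
  transitions through the product integral gives exactly the
  Aalen–Johansen estimator of `P(s,t)`.
* **MSRSF** — `B` bootstrap trees; each node draws `K` candidate
  covariates with random cut points and keeps the split maximizing the
  two-sample log-rank statistic between daughters; terminal nodes carry
  the Nelson–Aalen estimator of their rows; tree estimators are averaged.
* **MSRIST** — cycle 1 fits `M` extremely randomized trees to the *full*
  training data. Each later cycle computes, for every imputable censored
  row, the ensemble-conditional distribution of its failure time given
  survival past its censoring time `c` — a discrete law on the pooled
  terminal jump grid in `(c, τ]` with residual mass `Ŝ(τ|z)/Ŝ(c|z)`
  assigned to "censored at τ" — then draws `M` independently imputed
  datasets and fits one tree to each. After the last cycle the `M`
  current trees form the ensemble; earlier cycles are discarded.

`n_cycles` counts *fitting rounds including the initial raw fit*, so
`n_cycles = 1` is a pure extremely-randomized ensemble and the default
`n_cycles = 5` performs four imputation refits. This convention makes the
degenerate identity exact: with `M = 1`, `n_cycles = 1` and an
unsplittable root, the MSRIST prediction *is* the raw Nelson–Aalen
estimator, which the tests assert bitwise.

### Risk sets and delayed entry

For clock-forward transitions out of a non-initial state, a subject is only
at risk after entering that state: all risk sets (Nelson–Aalen, log-rank
splitting, reverse-KM) use the counting-process form
`Y(u) = #{entry < u ≤ time}`. With `entry = 0` this reduces to the familiar
`#{time ≥ u}`. Without this correction the Aalen–Johansen estimator on
illness-death data is biased, and the closed-form agreement checks in the
test suite would fail.

### Imputation scope

Only censored rows still in the origin state at last contact are imputed.
A row censored because the subject exited to a *different* state is
structurally unobservable for this transition — imputing it would fabricate
a counterfactual event time — so it stays a cause-specific censoring. The
provenance of every row (`original`, `competing`, `imputed_event`,
`imputed_tau`) is recorded and partition-checked.

## Defaults and tunable parameters

| parameter | default | meaning |
|---|---|---|
| `K` | `⌊√p⌋` | candidate covariates per split |
| `nmin` | 6 events | minimum observed events per terminal node (ERMT) |
| `n0` | 6 cases | minimum unique cases per terminal node (bootstrap trees) |
| `B` | 1000 | bootstrap trees per transition (MSRSF) |
| `M` | 50 | trees per cycle (MSRIST) |
| `n_cycles` | 5 | fitting rounds including the raw fit |
| `n_cuts` | 1 | random cut points per numeric candidate |
| `split_fraction` | 0.67 | training share in the holdout harness |
| `tau_quantile` | 0.9 | upper limit of the Brier integration range |

`K`, the event minimum of 6, `B = 1000` and `M = 50` over 5 cycles are the
standard settings for these estimators; they are shared between methods so
comparisons are fair. One random cut point per candidate is the pure
extremely-randomized choice; raise `n_cuts` for greedier splits.
Categorical covariates split on a uniformly random nonempty proper subset
of the levels observed at the node. Log-rank ties between candidates break
by proposal order, which is seeded, so fits are exactly reproducible; every
stochastic unit (tree, imputation draw) takes its seed from the master seed
through a fixed counter scheme, making results independent of execution
order.

## Evaluation

The Brier curve for state `h` weights squared residuals
`(I{x_i(s) = h} − π̂_h(s|z_i))²` by IPCW: subjects past an observed
terminal transition get `1/Ĝ(t_i−)`, subjects still under observation get
`1/Ĝ(s)`, subjects censored before `s` contribute nothing. `Ĝ` is the
marginal reverse Kaplan–Meier estimator of the censoring distribution; a
covariate-conditional `Ĝ(·|z)` can be substituted by the user, but no
censoring regression is fitted by default since standard IPCW practice
(and the data situations this package targets) rarely identifies one.
Weights are truncated at 20 and grid points with `Ĝ = 0` are dropped with
a logged count. On uncensored data every weight is identically 1 and the
estimator reduces bitwise to the complete-data mean squared error.

The integrated Brier score uses the trapezoid rule over the pooled event
grid up to `τ*`, the 0.9 quantile of observed test times (the IPCW weights
are unstable beyond it), normalized by the grid span. Per-transition
evaluation scores the occupation of the destination state on that
transition's own clock, matching how per-transition results are usually
tabulated. The concordance index is Harrell's: usable pairs are those
whose ordering is determinable under censoring, score ties count 1/2, and
an evaluation with no usable pairs is reported as undefined rather than
0.5. The risk score is the ensemble cumulative hazard at the training
set's median event time — a horizon that uses no test information.

VIMP uses the random-daughter scheme: test cases are dropped down each
tree with every split on the scored covariate replaced by a fair coin;
the VIMP is the increase in integrated Brier score, averaged over 10
randomization draws by default, with the Monte Carlo spread reported. A
covariate never used in any split short-circuits to exactly 0.

### Checking the Markov assumption

Fitting a downstream transition with the state-entry time `d` added to the
covariates (`markov_mode = "sojourn_augmented"`, or
`augment_sojourn = TRUE` at extraction) and reading the VIMP of `d`
operationalizes a Markov check: under a Markov process `d` carries no
information and its VIMP is statistically null; under strong semi-Markov
dynamics it ranks first. Under a reset clock, `d` alone is injected —
`t − d` is the outcome clock itself and would be circular as a fitted
covariate.

## The synthetic cohort generator

`simulate_cohort()` draws, per subject, covariates, then competing latent
exit times from each occupied state by exact inverse-transform sampling of
`α_hj(t)·exp(β'z + γ·d)` (constant or Weibull baselines, per-transition
clock), then independent right censoring; the latent uncensored paths are
returned alongside for oracle checks. Competing exits use independent
latent clocks, which is innocuous here because only the intensities, not
the joint law, define the observable process.

The default `hivlike_scenario()` emulates the shape of a ten-year
registry cohort of a progressive infection → intermediate stage → death
process: staggered-entry administrative censoring (uniform over a 10-year
window), baseline rates 0.19 and 0.078 per year calibrated so that with
the default covariate effects about half the cohort has an observed first
transition and about a quarter of those an observed second (at the
2473-subject reference size: roughly 1249 and 292 events). Ten covariates
mimic a typical registry mix — six binary (including treatment and a rare
co-infection), one three-level categorical, three continuous — of which
exactly three carry signal: a standardized immune-status marker
(`cd4`, log-hazard ratio −1.0 on the first transition), treatment
(`haart`, −0.4 and −0.6) and co-infection (`tb`, +0.9 on the second
transition). The second transition runs on a reset clock. What the
generator does *not* emulate: correlated covariates, time-varying
covariates or effects, covariate-dependent censoring, or recurrent
states — so passing tests demonstrate correctness of the machinery under
the stated model, not robustness to those features of real registries.

`markov_check_scenario()` is the matched pair for the sojourn check: its
second-transition intensity multiplies by `exp(0.35·d)` (strongly
semi-Markov) or is independent of `d` (Markov) with everything else
identical.

## Numerical choices

* Product-integral factors are applied at pooled event times only, in
  increasing order, with small-matrix products done in plain double
  arithmetic (no BLAS reassociation), so the single-transition case is
  *bitwise* the Kaplan–Meier product-limit complement. A time point whose
  hazard increments sum past 1 in a row is rejected by name.
* The illness-death closed forms use adaptive quadrature
  (`rel.tol = 1e-8` for the double integral); the test oracle is an
  independent 10⁵-step Riemann sum.
* Within-subject zero-length sojourns are invalid; tied times across
  subjects pool into single hazard jumps.
* Unseen categorical levels at prediction time route to the right
  daughter and are tallied.
* Conditional imputation laws renormalize away sub-1e-12 drift; a row
  whose conditional support is empty is kept as a censoring at `τ`, and a
  degenerate conditional (`Ŝ(c|z) = 0`) imputes an event at the first grid
  time after `c`, flagged.

## Problem sizes in the shipped checks

The test-suite and acceptance-script cohorts are sized for sharp yet quick
checks: oracle comparisons at n = 2000 (where the Aalen–Johansen sup error
against the closed form is ~0.02), ensemble behavior and planted-signal
recovery at n = 500 with `M = 10` trees over 3 cycles and 20 replicates,
the Markov check at n = 600 over 20 replicates per scenario, and the
evaluation harness at 5 train/test repeats. These choices keep the whole
validation reproducible in minutes on one CPU; the method defaults
(`B = 1000`, `M = 50`, 5 cycles, 500 repeats) remain what a full analysis
would use.

## Known limitations

* No recurrent states, interval censoring, or left truncation other than
  state-entry delays.
* Transition-probability prediction from a state *upstream* of a
  reset-clock transition is rejected rather than approximated: the entry
  time into that future state is unknown and the semi-Markov process has
  no Kolmogorov equations. Predict from the state itself (supplying its
  entry time), or fit clock-forward.
* `Ĝ` is marginal; strongly covariate-dependent censoring would bias the
  IPCW Brier score.
* Variance estimates for `Â` and `P̂` are not provided; uncertainty is
  assessed by repeated train/test splits.
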