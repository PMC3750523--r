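---
title: "Methods: delayed stochastic simulation of multimerizing gene products"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: delayed stochastic simulation of multimerizing gene products}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The simulation engine

`multinoise` implements an exact, event-driven stochastic simulation
algorithm with *delayed product release*: when a reaction fires, each of
its products may be held on a time-ordered waitlist and released a random
delay later. The next event is chosen by the direct method — an
exponential waiting time at the total propensity, then a reaction drawn
proportionally to individual propensities — and compared against the
earliest waitlist release; whichever comes first is executed, and all
propensities are re-evaluated. Because propensities are recomputed after
*every* event, state-dependent rate laws (the toggle switch's repression
function) are treated exactly, and because delayed products are withheld
from the state until release, non-Markovian steps such as multi-stage
transcription initiation are captured without approximating them by extra
species.

Mass-action propensities use the combinatorial convention
`k * prod_s choose(x_s, nu_s)`, so a homodimerization `2P -> D` with rate
constant `a` has propensity `a * x(x-1)/2`.

**Instant reactions.** Association rates set to `Inf` mark a reaction as
*instant*: it fires the moment its reactants are available. Instants are
resolved as a deterministic fixpoint after every state change, in a fixed
priority order — higher-order product first, ties by lexical order of the
first product species. The order matters only transiently (e.g. seven
monomers under a trimerization scheme resolve to two trimers and one
monomer under max-order-first priority); a fixed order makes runs exactly
reproducible. Each instant firing strictly consumes free assemblable
units, so the fixpoint terminates; a generous firing cap turns a genuinely
cyclic instant cascade into an error rather than a hang.

**Randomness.** All draws go through R's RNG, so a single
`seed` makes trajectories bit-identical. Sampling is on the grid
`0, dt, ..., t_end` (the transient from the empty state is included — the
systems do not reach equilibrium in finite time, and the stationarity
check below quantifies how little of a run the transient occupies); the
sample at a grid time is the state just before any event at exactly that
time.

## The gene-expression model and its parameters

Time is measured in protein lifetimes (`d_P = 1`). One gene is

* transcription: the start site `S` is consumed the instant it is free and
  released together with the transcript `M` after a shared interval
  `tau_S ~ Gamma(alpha_M, 1/(alpha_M * k_M))` — mean `1/k_M`, CV
  `alpha_M^(-1/2)`. The promoter is therefore occupied for the full
  interval, which is the renewal-process reading of multi-step initiation:
  integer `alpha_M` corresponds to `alpha_M` sequential exponential steps.
  `alpha_M = 1` yields Poisson mRNA (`M ~ Poi(k_M/d_M)`), larger values
  sub-Poissonian mRNA. (A note on conventions: we take CV in its standard
  sense, standard deviation over mean, which is the reading consistent
  with `alpha_M^(-1/2)`.)
* first-order mRNA decay at `d_M`; translation at `k_P * M` with an
  optional maturation delay `tau_P` (default 0 — for a single gene it only
  time-shifts the protein series; a truncated-normal `tau_P` is supported
  for robustness checks); first-order protein decay.

Multimerization follows the association lattice
`P_(k) + P_(n-k) -> P_(n)` for `2 <= n <= N`, `k <= n/2`, its reverse at
rate `u`, and subunit-wise degradation `P_(n) -> P_(n-1)` at `n * d_P`.
The default `a = Inf`, `u = 0` (instant, irreversible assembly) is the
reference condition for all sweeps; finite rates are supported and used in
the master-equation cross-check. Heterodimers couple two independent
genes; degradation of a dimerized subunit releases the surviving partner.

Every built system carries a bookkeeping species `X<i>` incremented by
translation and decremented by each subunit degradation. This makes the
identity `X_i = sum_k k * P_(i x k)` an *exact integer* invariant checked
at every sample of every sweep run, rather than a definition — any
stoichiometry bug in the multimer lattice breaks it immediately.

**Default grids.** The sweep drivers vary `k_M`, `d_M`, `k_P` over
`{0.1, 1, 10}` (one point per decade of the biologically motivated range
`[0.1, 10]` in protein-lifetime units) with `alpha_M = 1`, one long run of
`1e4` time units per point sampled every time unit. These sizes were
chosen so a full sweep runs in about a minute while leaving the Monte
Carlo standard errors (below) an order of magnitude smaller than the
effects being measured; denser grids, `alpha_M` in `{1, 2, 3, 5, 10}` and
`1e5`-unit runs reproduce the reference-scale computation via
`sweep_config()`.

## Statistics

* `eta()` is the squared coefficient of variation (population variance
  over squared mean) of a count series — zero for a constant series.
* `gain()` is tested/null for a statistic, with delta-method propagation
  of Monte Carlo errors. Standard errors come from **batch means** (20
  contiguous batches by default), since samples from one long trajectory
  are autocorrelated and naive errors would be optimistic. Statistics pool
  all samples including the transient, mirroring the sampling protocol; a
  `burn_in` option exists for sensitivity checks.
* `cross_correlation()` is Pearson-normalized (mean-centered, scaled by
  both standard deviations) on a signed lag grid. The pair analyzed in the
  sweeps is the total expressed subunit count `X1` against the multimer
  `P1xN`: under instant association the free-monomer count is only the
  residue `X1 mod N` and carries almost no signal, whereas `X1` is the
  quantity transcriptional regulation actually drives. The decay
  *half-life* is the smallest lag at which the symmetrized correlation
  `(cc(+l)+cc(-l))/2` first reaches half the zero-lag value, located by
  linear interpolation between grid points (no interpolation rule is
  canonical; linear is the least structured choice on a 0.1-unit grid).
  `NA` is returned when the correlation does not decay that far within
  `max_lag`.
* `mean_switching_time()` classifies samples by the strict comparison of
  the two repressor multimer counts. Ties go to the incumbent state: at
  low copy numbers equality is frequent, and counting ties as switches
  would inflate the switch count with spurious zero-length dwells. Dwell
  times are counted over completed dwells only; runs with fewer than two
  switches raise an error, which the toggle sweep records as a flagged
  row (such a run right-censors the dwell time at the run span).
* `stationarity_fraction()` compares, per sampling time, the
  cross-replicate count distribution against the final-time distribution
  (two-sample KS at level 0.05) and reports the fraction of times not
  rejected — a direct check of how much of a run is spent effectively at
  equilibrium.

## Model comparisons

Gains are always quoted against an explicitly simulated null model with a
shared per-row seed (paired seeds reduce the Monte Carlo variance of the
ratio; disable by re-running the null with a different base seed). The
conventions follow the comparisons the analysis is built around:

* homodimer vs monomer at identical parameters (so the mean gain of the
  dimer is bounded by one half);
* heterodimer vs a homodimer with **doubled** `k_M` (two genes feed the
  heterodimer, one the homodimer), both gauged against the single-rate
  monomer `X1`;
* compensated order-`N` homomer with `k_M` scaled by `N` vs the monomer,
  so the functional-unit means match at high expression. The scaling
  factor `N` parallels the heterodimer doubling; the exact compensation
  rule is an open choice, and `N`-fold scaling targets the multimer mean
  rather than the total-subunit mean.

The toggle switch uses the reference parameterization `d_M = 6`,
`k_M/(N d_M) = 5`, `k_P = 5`, `alpha_M = 1`, `K = 25 C`, with `k_M` scaled
by `N` so the regulatory-multimer means are comparable across orders.
Transcription under repression is implemented as a Markovian propensity
`k'_M / (1 + P_rep/K)` re-evaluated after every event, with no promoter
occupancy and zero release delay: for exponential (`alpha_M = 1`)
initiation this coincides in law with the delayed renewal formulation,
while for `alpha_M != 1` a state-dependent rate has no unambiguous
event-wise meaning mid-interval, so such parameters are rejected rather
than approximated.

## The interval-fit machinery

`fit_interval_models()` fits transcription-interval samples by maximum
likelihood under (a) a gamma distribution (via `fitdistrplus`) and (b) a
three-stage hypoexponential — a *sequential* sum of three exponentials,
the natural reading of multi-step initiation. The hypoexponential density
uses the classical partial-fraction form for distinct rates; near-equal
rates are kept apart by a relative `1e-8` perturbation (the likelihood
cost of that gap is far below estimation noise) and the optimizer runs
from several starts (Erlang-like equal rates and spread rates) to avoid
the flat ridge near the Erlang limit. Degenerate samples (zero variance)
are rejected: the gamma MLE diverges there. The two raw log-likelihoods
are compared directly, matching how the original comparison was reported;
note the hypoexponential has one more parameter, so on gamma-generated
data the preference margin is small.

## The synthetic genome-wide fixture

`generate_protein_fixture()` emulates the *structure* of genome-wide
per-gene protein statistics: an essentiality flag (12% essential by
default, the approximate genome-wide proportion), a homogeneous-subunit
count drawn from class-specific distributions skewed toward multimers for
essential genes, lognormal mean abundances that are higher for essential
genes and increase mildly with subunit count, and noise
`eta ~ floor + scale/mu` with lognormal scatter — low-copy-number noise
decaying into a noise floor attributed to extrinsic fluctuations. It is a
stand-in for exercising `summarize_multimers()` and is labelled synthetic
throughout: it reproduces the qualitative orderings (essential genes more
abundant and more multimerized; noise decreasing with abundance to a
floor) but none of the measured values, correlations between covariates,
or the heterogeneous-complex assignments of real data, so tests passing
on it certify the summarizer's arithmetic, not any biological claim.

## Numerical and design notes

* Truncated-normal delays are sampled by rejection (the default
  parameterizations keep the acceptance rate near one).
* The engine refuses non-finite or negative propensities naming the
  offending reaction, and treats a would-be negative count as an internal
  stoichiometry error.
* The engine's exactness is tested two ways: closed forms (birth-death
  Poisson, analytic stationary means, delay-shift identities) and a dense
  master-equation enumeration of a small finite-rate homodimer system,
  built independently from the closed-form propensities and compared by
  chi-square on the joint (mRNA, monomer, dimer) stationary distribution.
* KS checks against a discrete reference (Poisson) use the two-sample
  form against an exact reference draw; the one-sample KS against a
  continuous CDF is invalid under ties.
* Sweep rows are restartable: each records the derived seed that exactly
  reproduces it in isolation.

## Limitations

* No cell division or partitioning noise, no spatial effects, no
  tau-leaping acceleration — runs are exact and scale linearly in event
  count, which is the binding cost at the high-expression corners.
* The toggle switch requires `alpha_M = 1` (see above).
* Extrinsic noise enters only through the fixture generator's noise
  floor, not the mechanistic models.
* At deep repression the toggle's dwell times can exceed any fixed run
  length; the sweep reports such runs as censored rather than
  extrapolating.
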