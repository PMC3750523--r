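# multinoise

Stochastic simulation and analysis of how **protein multimerization** shapes
the abundance and temporal variability of functional protein complexes.

Many proteins are functional only as dimers, trimers, or higher-order
homomers (or as heterodimers of two gene products). Assembly of those
complexes is itself a stochastic process layered on top of noisy gene
expression, so it changes the mean number of functional units, their
cell-to-cell variability, and how tightly complex numbers track the
transcriptional signal that regulates them. `multinoise` is for systems
biologists who want to quantify those effects with exact stochastic
simulations: it provides a delayed-SSA engine, builders for the standard
gene-expression and multimerization reaction systems, the statistics used
to compare them, and reproducible parameter-sweep drivers.

## The model

Expression of one gene, in units of the protein lifetime (d_P = 1):

```
S   --inf-->  S(tau_S) + M(tau_S)     tau_S ~ Gamma(alpha_M, 1/(alpha_M k_M))
M   --d_M-->  0
M   --k_P-->  M + P(tau_P)
P   --d_P-->  0
```

Transcription is a renewal process: the start site `S` is consumed the
moment it is free and released, together with the transcript, after a
gamma-distributed interval with mean `1/k_M` and coefficient of variation
`alpha_M^(-1/2)`. `alpha_M = 1` gives Poisson mRNA numbers
`M ~ Poi(k_M/d_M)`; `alpha_M > 1` models the multi-step nature of
transcription initiation and gives sub-Poissonian mRNA statistics.

Order-`N` homomers add, for every `2 <= n <= N`, `k <= n/2`:

```
P_(k) + P_(n-k)  --a-->  P_(n)        (association; instant when a = inf)
P_(n)  --u-->  P_(k) + P_(n-k)        (dissociation)
P_(n)  --n*d_P-->  P_(n-1)            (degradation of any one subunit)
```

Heterodimers couple two independently transcribed genes through
`P1 + P2 <-> P12`, with either subunit degrading while dimerized. A
multimer-regulated toggle switch makes each gene's transcription rate
`k'_M / (1 + P_rep/K)`, where `P_rep` is the other gene's order-`N`
homomer.

The key statistics are the noise `eta = variance / mean^2` of a copy-number
series and the **gain**, the ratio of a statistic (mean or `eta`) in a
tested model to the same statistic in a null model. `X1 = sum_k k*P_(k)`
denotes the total subunit count regardless of form, and `Y1 = sum_k P_(k)`
the functional count when every form is functional. The temporal side is
measured by the zero-lag cross-correlation between `X1` and `P_(N)` and its
half-life, and — for the toggle — the mean switching time between the
states `P1xN > P2xN` and `P1xN < P2xN`.

## Worked example: what dimerization costs

```r
library(multinoise)

p <- expression_params(k_M = 10, d_M = 1, k_P = 10, alpha_M = 1)
mono  <- simulate_reactions(build_monomer_gene(p), t_end = 1e4, seed = 1)
dimer <- simulate_reactions(build_homomer_system(p, multimer_params(2)),
                            t_end = 1e4, seed = 1)

x1 <- series_stats(species_series(mono, "X1"))
d  <- series_stats(species_series(dimer, "P1x2"))
gain(d$mean, x1$mean, d$se_mean, x1$se_mean, statistic = "mean")
#> mean gain: 0.4975 (tested 49.67 / null 99.84), MC se 0.0032
gain(d$eta, x1$eta, d$se_eta, x1$se_eta, statistic = "eta")
#> eta gain: 1.011 (tested 0.05919 / null 0.05856), MC se 0.037
```

At high expression (mean of ~100 monomers) the dimer count is half the
monomer count (mean gain 0.5) while its noise is no worse than the
monomer's (eta gain ~ 1): dimerization halves the mean but, in this
regime, adds essentially no variability. At low expression the mean gain
drops below one half and the noise gain rises far above one — the sweep
drivers (`run_homodimer_sweep()`, `run_heterodimer_sweep()`,
`run_higher_order_sweep()`, `run_crosscorr_sweep()`, `run_toggle_sweep()`)
map these regimes over log-spaced parameter grids.

Interval-distribution fitting, for deciding whether measured transcription
intervals look gamma or like a chain of three exponential steps:

```r
set.seed(20)
fit_interval_models(rgamma(1e4, shape = 2.27183, scale = 1070.57))
#> interval fit on 10000 samples
#>   gamma:   shape 2.3087, scale 1056.4  (loglik -86396.3871)
#>   3-exp:   rates 0.00086122, 0.00086132, 0.0084845  (loglik -86406.5845)
#>   preferred: gamma
```

A thin command-line wrapper over the sweeps is installed at
`inst/scripts/multimer-sweep.R`
(`Rscript multimer-sweep.R homodimer --config cfg.yaml --out results/`).

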