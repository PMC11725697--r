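# amim — abundance-mediated species interaction models

`amim` fits hierarchical Bayesian models in which the occupancy or abundance
of one species depends on the **latent abundance** — not the mere
presence/absence — of one or more other species, using ordinary unmarked
detection/non-detection data (camera traps, track plates, repeated
detection surveys). It is aimed at ecologists studying directed species
interactions (intraguild predation, competitive suppression, facilitation)
who have site × occasion detection histories and a priori hypotheses about
who affects whom.

## The model

Sites `i = 1..I` are surveyed on `j = 1..J` occasions; each occasion
aggregates `K` subsamples into a count `y[i,j] ∈ 0..K`. A dominant species
follows a Royle–Nichols abundance model:

    N_i ~ Poisson(λ_i)                log λ_i  = β₀ + Σ β_m x_im
    p_ij = 1 − (1 − r_ij)^N_i         logit r_ij = α₀ + ...
    y_ij ~ Binomial(K, p_ij)

so heterogeneity in site-level detection identifies latent abundance even
though individuals are unmarked. A subordinate species may be modelled the
same way or as a standard occupancy model, `z_i ~ Bernoulli(ψ_i)`,
`y_ij ~ Bernoulli(p_ij · z_i)`. Directed interactions enter downstream
linear predictors through the realized upstream abundance:

    logit ψ_i^S = β₀ + β₁ x_i1 + γ₀ N_i^D + γ₁ N_i^D x_i2

with any acyclic multi-species graph of such edges (state or detection
targets, optional environmental modifiers, year-specific intercepts for
stacked multi-year designs). A one-flag variant replaces `N` by the
indicator `1{N > 0}` — the conventional co-occurrence treatment — so the two
readings of the same data can be compared directly. Inference is by a
purpose-built Metropolis-within-Gibbs sampler (compiled core): exact
categorical updates for latent `N` on `0..nMax`, closed-form updates for
`z`, adaptive random-walk Metropolis for coefficients, Normal(0, 2.5)
priors by default.

The package also ships the generative simulator, preset scenarios mirroring
the published simulation studies, Gelman–Rubin/ESS diagnostics, Pearson-χ²
posterior predictive checks, and a batch simulate–fit–evaluate harness
(relative/absolute bias, coverage, Type S/M classification, convergence
filtering).

## A worked example

```r
library(amim)

scenario <- presetStudy2(I = 300, J = 4)      # two species, gamma0 = -1
sim <- simulateDataset(scenario, seed = 42)   # data + latent truth
fit <- fitModel(scenario@graph, sim$data, mcmcConfig(seed = 7))
posteriorSummary(fit)
```

```
         parameter   mode   mean    sd   lo95   hi95  rhat rhatUpper     ess
1      D_state_int -0.041 -0.021 0.083 -0.189  0.139 1.001     1.007 1009.07
2        D_det_int  0.067  0.025 0.111 -0.200  0.242 1.002     1.008  908.46
3      S_state_int  0.748  0.850 0.228  0.425  1.313 1.016     1.057  608.44
4 S_state_gamma0_D -1.022 -1.050 0.209 -1.466 -0.658 1.010     1.035  655.77
5        S_det_int  0.059  0.037 0.098 -0.154  0.225 1.001     1.001 1896.59
```

The dominant species was simulated with mean abundance 1 (`D_state_int = 0`)
and individual detection probability 0.5 (`D_det_int = 0`); the interaction
truth is `γ₀ = −1`. The posterior mode −1.02 with 95% CrI [−1.47, −0.66]
recovers it, `isConverged(fit)` is `TRUE` (every Gelman–Rubin upper CI
< 1.1), and the solved subordinate intercept (0.95, chosen so mean occupancy
is 0.5 under the interaction) sits inside its interval. Fitting the same data
with `asOccupancyMediated(scenario@graph)` gives the presence/absence
reading of the interaction for comparison; replicate-level comparisons are
automated by `runStudy()`.

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/amim.R simulate --preset study1 --lambda-d 0.5 --seed 7 -o data/
Rscript inst/cli/amim.R study --preset study1 --lambda-d 0.5 --variants both --reps 25 --seed 1 -o study/
```

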