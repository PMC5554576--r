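---
title: "Bayesian variable selection in the grouped-data Cox model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian variable selection in the grouped-data Cox model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coxssvs)
```

# The model

`coxssvs` fits a Bayesian semiparametric proportional hazards model for
right-censored survival data with many more features than subjects (gene
expression against overall survival is the motivating setting), performing
variable selection inside the sampler rather than post hoc.

**Grouped likelihood.** The time axis is partitioned at the observed event
times, `0 = s_0 < s_1 < ... < s_J`, with the last interval chosen so that the
largest event time sits at its midpoint.  Writing `R_j` and `D_j` for the risk
and event sets of interval `j` and `h_j` for the hazard increment accumulated
over that interval, the likelihood is

```
L(D | beta, h) = prod_j exp( -h_j * sum_{l in R_j \ D_j} e^{x_l' beta} )
                        * prod_{l in D_j} ( 1 - exp( -h_j e^{x_l' beta} ) ).
```

Intervals are half-open `(s_{j-1}, s_j]`; a subject is at risk in interval `j`
iff its observed time exceeds `s_{j-1}`.  Tied event times share one break, and
a censoring time beyond the last break gets one extra event-free tail interval.
All likelihood arithmetic is done in log space, with `log1p`/`expm1` handling
the `1 - exp(-x)` factors, so very small hazard increments do not underflow.

**Baseline hazard prior.** The increments `h_j` get independent gamma priors
`G(alpha_{0j} - alpha_{0,j-1}, rate c0)` with `alpha_{0j} = c0 * H*(s_j)`,
where `H*(t) = eta0 * t^kappa0` is a Weibull initial guess for the cumulative
baseline hazard.  `(eta0, kappa0)` are calibrated by ordinary least squares of
`log H(t)` on `log t` over the jump points of the Nelson-Aalen estimator of
the training data; `c0` (default 2) expresses how much weight that initial
guess carries.  Reading the second gamma argument as a *rate* makes the prior
mean of `h_j` equal exactly the `H*` increment of its interval; reading it as
a scale would not, so the rate convention is used throughout.

**Spike-and-slab prior and selection.** Each coefficient has the two-component
mixture prior `beta_i | gamma_i ~ (1 - gamma_i) N(0, tau^2) + gamma_i
N(0, cb^2 tau^2)` with latent inclusion indicators `gamma_i ~
Bernoulli(pi_i)`.  Defaults `tau = 0.0375`, `cb = 20` put the slab standard
deviation at `cb * tau = 0.75`, i.e. roughly a `[-1.5, 1.5]` range for an
included log-hazard ratio, while the spike keeps excluded coefficients within
a few hundredths.  The posterior mean of `gamma_i` is the feature's posterior
inclusion probability; the reported model selects the `p_m` top-probability
features, where `p_m` is the rounded average model size across iterations —
a data-dependent cutoff that respects the prior setup instead of a fixed
threshold.

**Selection priors.** `pi` may be uniform (`k/p`, expected model size `k`,
default `k = 20`), proportional to a secondary data source
(`pi_i = k * sigma_i / sum(sigma)`, e.g. per-gene copy-number standard
deviations across patients — features whose copy number varies more are more
plausible survival drivers), or set to the simulation-study patterns (0.8 on
a designated set, 0.1 elsewhere).  Constructed priors are clipped to
`[1e-6, 1 - 1e-6]` so no Bernoulli conditional is ever exactly degenerate.

# The sampler

A Gibbs cycle updates `beta` (coordinate-wise adaptive random-walk
Metropolis-Hastings), then `gamma` (exact Bernoulli conditionals), then `h`
(near-conjugate gamma proposals with a Metropolis correction).  The chain
starts from the empty model (`beta = 0`, `gamma = 0`, `h` at its prior mean).

Three numerical choices deserve comment.

**Two beta kernels.** By default the acceptance ratio for `beta_i` uses the
spike-and-slab prior *conditional on the current* `gamma_i` — the canonical
stochastic-search update.  Its characteristic dynamic is that a coefficient
can only grow out of the spike through rare joint excursions (`beta_i`
drifting to the spike's edge, `gamma_i` flipping on, `beta_i` then climbing
in the slab), so at moderate run lengths the small inclusion probabilities
of weak or proxy variables are explored conservatively — a finite-length
dynamic worth keeping in mind when comparing published selection sizes
from this sampler family, which can sit far below what the prior marginal
alone implies.  Because the likelihood does not involve `gamma`,
`chain_config(collapse = TRUE)` instead marginalizes the indicator out of
the prior term (`(1 - pi_i) N(0, tau^2) + pi_i N(0, (cb tau)^2)`) and
redraws `gamma_i | beta_i` exactly afterwards — a collapsed Gibbs step with
the identical joint posterior but no spike-slab barrier, reaching
equilibrium roughly an order of magnitude faster.  Both kernels are checked
against exhaustive enumeration with quadrature on small models; on
high-dimensional correlated designs the collapsed chain typically reports
larger mean model sizes because it actually visits the many
moderate-probability proxy configurations.

**Adaptation.** Each coordinate has its own proposal scale, multiplicatively
adapted every 100 iterations during burn-in toward a 35% acceptance rate with
a diminishing step (`min(0.25, 1/sqrt(batch))`), then frozen, so the
post-burn-in kernel is a fixed Markov kernel with the correct target.

**Exact hazard updates.** The gamma full conditional with shape
`alpha-increment + d_j` (`d_j` = events in interval `j`) and rate
`c0 + sum_{R_j \ D_j} e^{x'beta}` is exact only under the linearization
`1 - e^{-h e} ~ h e` of the event factors.  It is used here as a proposal,
with the cheap Metropolis ratio
`prod_{D_j} [(1 - e^{-h' e}) / h'] / [(1 - e^{-h e}) / h]` restoring the
exact target.  With one event per interval — the typical case — `h_j e^{x'beta}`
is of order `1/|R_j|` and essentially every proposal is accepted, but on
coarse partitions the correction measurably matters (small-model enumeration
puts the uncorrected bias in posterior inclusion near 0.03).  On the `d_j`
ambiguity (events vs censorings in the interval): the grouped-likelihood
construction pairs `h_j` with the interval's *event* factors, so `d_j` counts
events.

The production path is compiled (Rcpp/RcppArmadillo) with the linear
predictor maintained incrementally (O(n) per coordinate update); a pure-R
engine implements the identical kernels through the identical random-number
stream, so `run_chain(..., engine = "R")` reproduces the compiled chain
bit for bit and serves as the reference in tests.

# Parallel tempering

`run_parallel_tempering()` runs a ladder of chains whose spike-and-slab
`tau` is multiplied by `T^ch` on a log-linear temperature scale (`T >= 1`,
chain 0 untempered).  Only the prior is broadened; the likelihood is shared.
Every 10th iteration a uniformly chosen adjacent pair proposes to exchange
complete states `(beta, gamma, h)`, accepted with the usual two-chain
Metropolis ratio — which, because everything except the `beta | gamma` prior
is common, reduces to spike-and-slab prior terms at the two states.  The
ladder ratio is tuned by short pilot runs (bisection on `log(T - 1)`) toward
the upper end of the 20–50% swap-acceptance band commonly recommended for
parallel tempering; the reported swap acceptance is accepted over attempted
swaps across the whole run.
Chain count defaults to 6 (a configuration knob).  With a flat ladder
(`T = 1`) every swap is accepted and the output is distributionally identical
to the plain sampler, which the tests check.

# The synthetic-data generator

`make_scenario()` / `simulate_survival_data()` emulate a high-dimensional
genomic survival study: `n = 200` subjects, `p = 500` standard-normal
features in blocks of `m = 100` with within-block correlation `rho^|i-j|`
(`rho = 0.5`, exact AR(1) recursion), and Cox-Weibull event times by
inversion, `T* = [-log U / (eta e^{x'beta})]^{1/kappa}`.  The Weibull
baseline is fixed by two survival constraints, `S(12) = 0.9` and
`S(36) = 0.5` — the only monotone pairing of the printed values (the reverse
assignment implies survival increasing with time and is rejected by
`weibull_from_quantiles()`'s `kappa > 0` precondition).  The *sparse*
scenario has true coefficients `(0.75, -0.75, 0.5, -0.5, 0.25, -0.25, 0,
...)`; the *nonsparse* scenario draws 122 coefficient magnitudes uniformly
from `(0.2, 0.8)`, 61 of each sign, on the first 122 features.

Censoring is an uninformative mixture of administrative (uniform on
`(0, a_max)`) and exponential loss to follow-up.  The mixture parameters are
not dictated by the design, so they were calibrated once — `a_max = 160`,
rate `1/500` — to give a realized censoring fraction near 30% at study
conditions (across seeds roughly 0.31–0.35), a typical oncology-cohort rate,
and are exposed as scenario knobs.

**What the generator does and does not emulate.** It reproduces the
dimensions, correlation blocks, effect patterns and censoring mechanism of
the study design, which is what the sampler and evaluation machinery need.
It does not emulate heavy-tailed expression distributions, batch effects,
informative censoring, or covariate measurement error, so passing tests here
do not certify behavior under those real-data features.

One property of the stated sparse design is worth flagging: the six true
coefficients alternate in sign while sitting adjacent in a positively
correlated AR(1) block, so their *marginal* effects partially cancel
(the single-variable association of the `beta = 0.75` feature is roughly
halved).  On typical draws the correct posterior therefore gives the
`|beta| = 0.5` predictors only modest inclusion probabilities under the
uniform prior, and posterior summaries vary noticeably across data seeds.
The package reports whatever the posterior actually is; users comparing
against published summary tables for this design should expect
draw-to-draw variability.

# Prediction and evaluation

The selected model predicts survival by plugging in posterior means:
`S(t | x) = exp(-H0(t) e^{x_sel' beta_sel})` with `H0` the step cumulative
sum of posterior-mean interval hazards and `beta` restricted to the selected
set.  This uses only quantities the sampler already produced; a
refit-with-selected-variables mode (`mode = "refit"`, all selected features
forced into a short second chain) is available for comparison, since either
convention is defensible.  Prediction error is the Graf-style Brier score
with inverse-probability-of-censoring weights from the Kaplan-Meier estimate
of the censoring distribution on the test set, evaluated on the grid of
unique test event times up to `t_max = 80` plus endpoints; the integrated
Brier score is its trapezoid time average, and the covariate-free
Kaplan-Meier curve of the training data is the reference predictor.
Subjects censored before an evaluation time contribute through the weights
only, and terms with a zero censoring weight are dropped, per the standard
convention.

# Diagnostics

`trace_summaries()` assembles per-iteration log-likelihood (stored by the
sampler and verified in tests against recomputation from the stored states),
model size and the L2 norm of `beta`; `running_means()` and
`effective_sample_size()` (autocorrelation sum with initial-positive-sequence
truncation; a constant series reports 0) cover per-coefficient mixing.

# Problem sizes used in the shipped studies

`run_scenario_study()` runs the full study conditions (`n = 200`,
`p = 500`) with 20,000 iterations, burn-in 5,000 and thinning 5 — the
log-likelihood and model-size traces stabilize within the first few
thousand iterations — and the tempering study uses 10,000 iterations across
6 chains with swaps every 10th iteration.  Unit tests use much smaller
models (`p` up to 30) where exhaustive or quadrature oracles are available.

# Known limitations

Left truncation, competing risks, time-varying covariates and hyperpriors on
`tau`, `cb` or `pi` are out of scope.  The selection cutoff `p_m` rounds a
posterior mean and can be unstable when the model-size posterior is flat.
The plug-in predictor ignores posterior uncertainty in `beta` and `h`
(a deliberate choice; the refit mode shares it).  Status codes other than
0/1 are rejected rather than reinterpreted.
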