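---
title: "Attributing prediction error to stochasticity, nonlinearity, and chaos"
author: "edmchaos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing prediction error to stochasticity, nonlinearity, and chaos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edmchaos)
```

## The problem

A forecast of an ecological time series can fail for three qualitatively
different reasons. *Stochasticity* — process noise such as demographic or
environmental variability — is unpredictable at the level of individual
observations no matter how good the model is. *Nonlinearity* — dynamics
whose local behavior depends on where the system sits in state space —
defeats any single linear approximation but remains predictable with a
state-dependent model. *Chaos* — sensitive dependence on initial
conditions — makes even a perfect model useless beyond short horizons,
because infinitesimal state errors grow exponentially. Replicated
experiments whose runs differ **only in their initial abundances** are the
ideal setting to separate these signals: under identical conditions,
divergence between replicates can be attributed to the dynamics rather
than to environmental differences.

`edmchaos` implements the full chain: nonparametric (EDM) forecasting,
cross-prediction between replicates, Lyapunov-exponent estimation from the
growth of forecast error with horizon, and a partition of mean squared
prediction error into the three fractions.

## Forecasting machinery and its assumptions

Both forecasters operate on a state-space embedding of a series sampled on
a regular grid. In the univariate mode the state at time $t$ is the lag
vector $(x_t, x_{t-\tau}, \dots, x_{t-(E-1)\tau})$; in the multivariate
block mode it is the simultaneous abundance vector of all species, which
for a closed two-species system gives the theoretically expected $E = 2$.
The two modes are equivalent reconstructions of the attractor in theory;
both are exposed because their finite-sample skill can differ.

**Simplex projection** forecasts a query state as the weighted average of
the futures of its $E + 1$ nearest library neighbors, with weights
$w_i = \exp(-d_i / d_1)$. It assumes only continuity of the dynamics and
is used to select $E$ (leave-one-out MAE, smaller $E$ wins ties).

**S-map** fits, at every query, a weighted linear regression of the
targets on the states with weights $w_i = \exp(-\theta\, d_i / \bar d)$,
$\bar d$ the mean distance from the query to *all* library states. At
$\theta = 0$ every state gets equal weight and the S-map collapses to one
global linear autoregression — this identity anchors the "total variation"
of the error partition, and the test suite asserts it to $10^{-10}$. As
$\theta$ grows the regression localizes; skill improving with $\theta$ is
therefore direct evidence of state-dependent dynamics. The per-query
coefficients of a block-mode S-map are time-varying interaction
coefficients: the coefficient of the predator dimension in the regression
forecasting prey is the local effect of predators on prey.

Multi-horizon forecasts are **direct**: each horizon $tp$ is its own
regression onto the target shifted by $tp$, not an iterated one-step map.
Series are not normalized before embedding, so forecasts are in abundance
units and unit choices matter when species are pooled.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `E_grid` | 1–8 | candidate embedding dimensions (univariate mode) |
| `tau` | 1 grid step | embedding lag |
| `horizons` | 1–10 grid steps | forecast horizons for cross-prediction and λ |
| `theta_grid` | 0 … 8 (18 values) | S-map localization candidates; must include 0 |
| `step` | 0.5 or 1 day | spline regularization grid (short vs long series) |
| `E_fixed` | 2 | embedding dimension for cross-prediction (two species) |
| `lambda_horizons` | (1, 2) | horizon pair whose RMSE growth defines λ_est |
| `chaos_formula` | `"squared"` | see below |

Cross-prediction fixes $E = 2$ for every pair so that pairs cannot fail
merely because their individually selected dimensions disagree; θ is
selected on the **source** replicate by leave-one-out (the trained
algorithm, including its hyperparameter, travels to the target).

## The error partition

For one series, with leave-one-out fits at horizon 1:

1. $\mathrm{MSE}_{\theta=0}$ — the error of the single global linear model
   ("total variation" net of linear deterministic structure).
2. $\mathrm{MSE}_{best\theta}$ — the minimum over the θ grid. The
   difference is the **nonlinearity** component: error a state-dependent
   model removes.
3. $\lambda_{est}$ — the best-θ fit is re-run at the horizons in
   `lambda_horizons` and
   $\lambda_{est} = \log(\mathrm{RMSE}_{t+1}/\mathrm{RMSE}_t)$ (per-step
   rates averaged when more than two horizons are supplied). Growing error
   means divergence; shrinking error means local stability.
4. The **chaos** component is the part of $\mathrm{MSE}_{best\theta}$
   attributable to divergence. Writing the implied non-chaotic error as
   $\mathrm{RMSE}_0 = \mathrm{RMSE}_{best\theta} e^{-\lambda_{est}}$, the
   chaos component is
   $\mathrm{MSE}_{best\theta} - \mathrm{RMSE}_0^2 =
   \mathrm{MSE}_{best\theta}\,(1 - e^{-2\lambda_{est}})$ — the
   `"squared"` formula and the package default. The widely quoted
   single-exponent simplification $(1 - e^{-\lambda_{est}})$ mixes an
   RMSE-scale factor into an MSE-scale equation; it is retained as
   `chaos_formula = "printed"` for comparability. The choice matters: with
   the single-exponent factor, the chaos component can exceed the
   stochastic remainder only when $\lambda_{est} > \log 2$, a bar that
   even strongly chaotic one-dimensional maps (Ricker at $r = 3$,
   $\lambda \approx 0.39$; logistic at $r = 4$, $\lambda = \log 2$
   exactly) cannot clear, so the partition would never call its own
   chaotic benchmark chaotic. The variance-consistent form classifies it
   correctly.
5. If $\lambda_{est} < 0$ the chaos component is exactly zero (convergence
   cannot contribute error). **Stochasticity** is the remainder. All three
   are divided by $\mathrm{MSE}_{\theta=0}$; the fractions are clamped to
   $[0, 1]$ and renormalized (with a flag) only if numerical edge cases
   require it, and they always sum to 1.

## What the generators emulate — and what they do not

`simulate_lv_replicates()` emulates the replicated-microcosm design:
Euler–Maruyama integration of one shared Lotka–Volterra parameterization,
with replicates differing only in initial abundances, additive process
noise, and abundances floored at zero so extinctions persist.
`simulate_map()` provides the discrete-time growth benchmarks: the Ricker
map $x_{t+1} = x_t e^{r(1-x_t)+\sigma\zeta_t}$ (multiplicative log-normal
noise, preserving positivity; chaotic for $r \gtrsim 2.69$, so $r = 3$ is
the chaotic benchmark) and the quadratic logistic map (additive noise,
clipped to $[0,1]$; $\lambda = \log 2$ at $r = 4$). `simulate_var1()` is
the linear stochastic benchmark whose coefficient matrix the θ = 0 S-map
must recover. The benchmark series use 100 steps (1000 for Lyapunov
regressions, 500 for VAR recovery) — long enough for stable EDM libraries,
short enough that the whole validation suite runs in minutes.

Real microcosm data differ in ways the generators do not capture:
observation error on top of process noise (available as an option but off
by default), irregular sampling (handled by the spline step, but the
generators emit regular grids), demographic discreteness at very low
abundances, and slow drifts in experimental conditions. Passing tests on
synthetic data therefore validate the estimators' correctness, not the
claim that any particular real system is chaotic.

## Numerical choices

* **Spline regularization** uses the classic cubic spline
  (`stats::spline`, `method = "fmm"`), which interpolates the observations
  exactly and reproduces polynomials up to cubic order; a natural spline
  (zero second derivative at the boundaries) cannot reproduce a cubic
  trend near the series ends, which is why it was not used. Interpolated
  abundances are floored at zero; the grid is anchored at the first
  observation and never extrapolates.
* **Weighted least squares** is solved by SVD with a relative
  singular-value cutoff of $10^{-10}$; rank-deficient designs get the
  pseudoinverse solution, and a design whose usable states are all
  identical is an error, not a silent constant fit.
* **Zero-distance neighbors** in simplex projection are averaged with
  equal weight (the $d_1 = 0$ limit of the weighting kernel).
* **Tie-breaking** in $E$ and θ selection prefers the smaller parameter.
  Candidates whose error is below $10^{-10}\times$ the data's standard
  deviation are treated as numerically exact ties (on noiseless linear
  data all θ fit to machine precision, and θ = 0 should win).
* **Leave-one-out** excludes library rows sharing the query's time stamp;
  no wider temporal exclusion window is applied. Cross-prediction between
  distinct replicates uses the full library (set `loo = TRUE` explicitly
  when the "other" replicate is a literal copy).
* **Degenerate inputs** error early with the offending replicate named:
  fewer than 4 points for the spline, series too short for the requested
  embedding, nonpositive RMSE in the λ equations, zero observed variance
  for the efficiency coefficient E2 (flagged, other metrics still
  returned).
* λ **p-values** are reported raw, matching the common practice of
  filtering at p < .05 without multiplicity adjustment;
  `stats::p.adjust` can be applied downstream if desired.

## Known limitations

* $\lambda_{est}$ from forecast-error growth conflates divergence with
  noise accumulation: in a stable stochastic *linear* system the direct
  2-step error already exceeds the 1-step error, so $\lambda_{est} > 0$
  and a nonzero chaos fraction appears even though the deterministic
  dynamics contract (the VAR benchmark in the test suite shows this; its
  nonlinearity fraction is correctly near zero, and stochasticity still
  dominates chaos). Chaos fractions for noisy systems are therefore upper
  bounds.
* Bounded populations force long-horizon λ estimates toward zero
  regardless of chaos, so λ is estimated from short horizons (default the
  1→2 step) where the linear-growth regime holds.
* The nonlinearity component inherits the θ grid: if the true optimal θ
  lies beyond the grid maximum (8), part of the nonlinear signal is
  counted as stochasticity.
* The phase-space grouping boundary is supplied by the analyst (a straight
  line in initial-abundance space, points on the line going to group 1);
  the package deliberately does not discover regime boundaries
  automatically.
* E2, MAE and MSE are computed in raw abundance units; comparing species
  with very different scales in pooled diagnostics weights the
  larger-scaled species more.

## A minimal run

```{r example, eval = FALSE}
series <- simulate_map("ricker", r = 3, sigma = 0.1, n_steps = 100,
                       seed = 42, burn_in = 20)
partition_series(series)

ds <- simulate_lv_replicates(list(c(5, 8), c(6, 10), c(12, 9)),
                             sigma = 0.05, n_steps = 40, seed = 1)
recs <- pairwise_table(ds, E = 2, horizons = 1:10)
head(as.data.frame(recs))
```
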