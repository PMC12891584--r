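---
title: "Methods: autumn senescence models with night-light forcing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: autumn senescence models with night-light forcing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alanphen)
```

# The problem

Autumn leaf senescence in temperate trees is triggered by accumulating cold
and shortening days. Artificial light at night (ALAN) interferes with the
photoperiod signal plants perceive, and city night-time radiance has grown
steadily over the satellite era. `alanphen` implements the modelling and
statistical machinery needed to ask whether ALAN shifts the date of foliar
senescence (DFS): process models with an ALAN forcing term, their
calibration and comparison, driver-sensitivity statistics, and projection —
all exercisable on synthetic data with known ground truth.

# The models and their assumptions

Four classical model families share one template: an **onset day** (the
first day at or after the boreal summer solstice, day 172, where the start
condition holds), a **daily forcing rate**, and a **threshold** whose first
crossing is the predicted DFS. Years in which the threshold is never
reached by day 365 are reported missing, never wrapped into the next year.

| family | onset condition | daily rate | threshold | params |
|---|---|---|---|---|
| CDD  | T < T_th | max(T_th − T, 0) | CDD_th | 2 |
| DM   | T ≤ T_b and P ≤ P_s | [T_b − T]₊^x · f(P)^y | Y_crit | 5 |
| SIAM | as DM | as DM | a + b·LUD_a | 6 |
| DMT  | as DM | as DM | a + b·Tss | 6 |

`P` is the astronomical day length from the declination / hour-angle
formula (declination 23.44°·sin(2π(284 + doy)/365), accurate to < 0.5°;
cos of the hour angle clamped to [−1, 1] so polar day/night degrade
gracefully). `f(P)` is either `P/P_s` or `1 − P/P_s` (clamped at 0); which
variant a dataset calls for is a configuration choice, never guessed.
`LUD_a` is the leaf-unfolding-date anomaly (centred on the calibration
years); `Tss` is the mean temperature over configurable spring–summer
months, default March–August.

Numerical choices in the rate: `[T_b − T]` is clamped at 0 *before*
exponentiation and `0^0` is defined as 0, so warm days contribute nothing
even when `x = 0` — real exponents on negative bases are undefined, and the
models describe cold-driven accumulation. The onset condition is
conjunctive for the DM family (both the temperature and the photoperiod
test must hold on the same day). A non-positive threshold (possible for
SIAM/DMT with hostile `a`, `b`) flags the year invalid rather than
crossing instantly.

**ALAN variants** multiply the daily rate by the annual coefficient
`ALANin_i = exp(k·(ALAN_i − ALAN_max)/ALAN_max)`, held constant within the
year (radiance is an annual composite) and normalized by the *per-site*
series maximum — the coefficient indexes years within the series it
modulates. With `k = 0` the variant reproduces its base model bit for bit
(a tested identity). Note the direction: when `k < 0` and the year is
dimmer than the brightest year, the exponent is positive, the multiplier
exceeds 1, accumulation is *faster* and DFS *earlier*; as ALAN grows toward
its maximum the multiplier decays to 1, so a rising-ALAN series with
`k < 0` produces a *delaying trend relative to the base model*. Only the
accumulation rate is modulated; onset determination is left untouched (the
alternative is not described by the template this follows).

# Calibration

Parameters are fitted by particle swarm optimization (PSO) minimizing the
RMSE between predicted and observed DFS, with a fixed additive penalty of
100 days for each observed year in which a candidate parameter vector never
crosses the threshold (this pushes the swarm away from degenerate regions
without hiding them). Defaults are the standard constriction values:
inertia 0.729, cognitive = social = 1.49445, 40 particles, 200 iterations.

Because predictions are integer days, the objective is piecewise constant
and a single swarm can stall on a plateau; `pso_config(restarts = )`
(default 5) runs independent swarms and keeps the best, which in our
recovery experiments raises the probability of hitting the global basin on
a noise-free CDD problem from ~1/3 per swarm to ~1. Bounds are handled by
reflection with velocity reversal, and every run is deterministic given its
seed. Parameter bounds: exponents `x, y ∈ [0, 2]`, `T_th ∈ [0, 50] °C`,
`k ∈ [−10, 10]` (wide enough that `exp(±10·relative gap)` spans any
plausible modulation).

Identifiability caveat: threshold models trade parameters off (a higher
`T_th` with a higher `CDD_th` predicts nearly the same days), so recovery
is asserted on the *prediction surface* — fitted predictions within 1 day
RMSE of the truth on noise-free data — not on the raw parameter vector.
With noisy observations, in-sample RMSE necessarily sits *below* the noise
sd (six parameters on twenty years absorb noise); model fidelity is
therefore judged against independent noisy realizations of the same truth,
where a well-calibrated model sits at the noise floor.

Model comparison uses Pearson *r* (two-sided t-test), the share of sites
significant at P < 0.05, RMSE, and `AIC = n·ln(SSE/n) + 2k` with `k` the
parameter count — the ALAN term must buy at least its 2-point penalty.

# Sensitivity statistics

All correlation inputs are **standardized anomalies**: residuals of an OLS
regression on year, scaled to unit sd, so interannual signal is separated
from shared trends. Trends themselves are estimated by the Theil–Sen
median-of-pairwise-slopes with the Mann–Kendall test (tie-corrected normal
approximation, continuity correction, no pre-whitening).

The **preseason search** anchors at the calendar month of the multi-year
mean DFS (inclusive), extends windows backwards 1–6 months (windows may
cross into the previous calendar year; explicit year–month indexing), and
selects the length maximizing |partial correlation| of the windowed driver
with DFS, controlling the other drivers averaged over the same window. Ties
break toward the shorter window (parsimony). Because the selection is a max
over six correlated candidates, the selected |r| is biased upward on pure
noise — a property the test suite verifies rather than hides; comparisons
across drivers use the same selection rule, so the bias is shared.

**Ridge sensitivities** are closed-form `(XᵀX + λI)⁻¹Xᵀy` on centred
variables (intercept unpenalized, vanishing by centring). λ defaults to 1.0
on standardized predictors: enough to stabilize the collinear
preseason-driver matrix, small enough that λ = 0 reproduces OLS exactly
when wanted. The **moving-window modulation** correlates 11-year window
means of ALAN with climate sensitivity at a 1-year step (a 22-year record
gives 12 windows). The **Gaussian response** `y = A·exp(−(x − x₀)²/w)` is
fitted by `nls` (port, `w` bounded positive) from the deterministic start
`A = y[argmax|y|]`, `x₀ = x[argmax|y|]`, `w = range(x)²/4` — no seeded
randomness in a deterministic fit — with a Nelder–Mead fallback that warns
on non-convergence.

The MAD outlier filter flags values deviating from the median by more than
2.5 × the raw MAD (no 1.4826 normal-consistency scaling). On Gaussian data
2.5·MAD ≈ 1.69σ, so the rule trims ~9% of clean normal scatter — it is a
gross-error filter, intentionally aggressive, and with MAD = 0 the strict
inequality flags nothing when all values are equal.

# The synthetic world

The generator states one world and keeps it: 22-year (2001–2022) records
for mid-latitude Northern-Hemisphere cities. Daily temperature is a
sinusoid peaking near day 200 (mean 10 °C, half-amplitude 12 °C) plus a
0.03 °C yr⁻¹ warming offset and AR(1) noise (coefficient 0.7, stationary
sd 2 °C, continuous across year boundaries). ALAN starts at
5 nW cm⁻² sr⁻¹ and grows 0.4 yr⁻¹ with sd-0.3 noise, floored at 0.
Leaf-unfolding dates are N(110, 6²) rounded; GDP grows 3% yr⁻¹ with
lognormal noise; monthly precipitation and shortwave follow seasonal
sinusoids with additive noise. Observed DFS is the truth model's
prediction plus iid Gaussian noise **rounded to whole days** (in-situ
records are daily); the Gaussian-iid choice is an assumption — the field
gives no distributional description of in-situ DFS noise. Calendars are
fixed 365-day years (Feb 29 dropped). A master seed spawns per-site
substreams through a counter-based hash, so site *i* is identical
regardless of `n_sites` or generation order.

What the generator does **not** emulate: satellite raster geometry, mixed
pixels, spatial autocorrelation between sites, cloud contamination, or any
sub-annual ALAN dynamics. A green test therefore establishes that the
algorithms are implemented correctly and behave as designed under the
stated statistical structure — not that the effect sizes or significance
rates transfer to real satellite or network data.

# Scaled-down test budgets

The model-selection simulation (50 sites, base vs ALAN variants, with and
without a true ALAN effect) and the parameter-recovery study run inside the
test suite with reduced swarm sizes (20–30 particles, 50–150 iterations,
2–5 restarts) to keep the suite around five minutes. The acceptance
thresholds themselves are the stated ones; only the compute budget is
scaled.

# Known limitations

- Calibration is per site; pooled calibration across cities is available
  through the same code path but off by default.
- The preseason controls use the same window as the driver under test;
  per-control optimal windows are not implemented.
- The ALAN–GDP projection regression is fitted pooled across sites (its
  coefficients are reported as single values); a single site degrades to
  ALAN ~ ln(GDP) and a constant-GDP single site is rejected as singular.
- No spring-phenology process model: leaf-unfolding dates are inputs.
- The moving-window climate sensitivity is computed from annual series
  windowed after the fact; recomputing ridge fits within each window is a
  straightforward extension not wired into `run_experiment()`.
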