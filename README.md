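# alanphen

Process-based modelling of the autumn **date of foliar senescence (DFS)**
under **artificial light at night (ALAN)**, for phenologists and global-change
ecologists who want to ask: does urban night-time lighting measurably shift
when leaves senesce, and does adding an ALAN term to a classical autumn
phenology model earn its extra parameter?

The package provides, as tested reusable building blocks:

- the four classical autumn senescence models and their ALAN-enhanced
  variants (below), returning full daily accumulation traces;
- particle-swarm calibration against observed DFS, with model comparison by
  Pearson *r*, significance share, RMSE and AIC;
- the sensitivity layer used around such models: MAD outlier filtering,
  Theil–Sen / Mann–Kendall trends, preseason-optimized partial correlations,
  ridge-regression driver sensitivities, 11-year moving-window modulation of
  climate sensitivity by ALAN, and a Gaussian sensitivity-vs-ALAN response
  fit;
- night-length astronomy (declination / hour-angle) for photoperiod and for
  disaggregating annual ALAN radiance to months;
- an ALAN ~ GDP regression for projecting future radiance, and century-scale
  DFS projection;
- a seeded synthetic-data generator that emulates the statistical structure
  of the real inputs so the entire pipeline is testable against known ground
  truth, plus an orchestrating `run_experiment()` and a small CLI
  (`inst/cli/alanphen.R`).

## Models

All models start accumulating on the first day at or after the boreal summer
solstice (day 172 of a fixed 365-day calendar) on which the start condition
holds, and predict DFS as the first day the accumulated state reaches a
threshold.

**CDD** (cooling degree days): with daily mean temperature `T(t)` and
threshold temperature `T_th`,

    CDD(t) = Σ max(T_th − T(t), 0),   DFS = first t with CDD(t) ≥ CDD_th

**DM** (Delpierre): daily rate combining cold and photoperiod `P(t)`,

    R_sen(t) = [T_b − T(t)]₊^x · f(P(t))^y,   f(P) = P/P_s  or  1 − P/P_s
    S_sen(t) = S_sen(t−1) + R_sen(t),          DFS = first t with S_sen ≥ Y_crit

with onset requiring `T ≤ T_b` and `P ≤ P_s`, exponents `x, y ∈ [0, 2]`.

**SIAM**: DM with `Y_crit = a + b·LUD_a` (spring leaf-unfolding-date
anomaly). **DMT**: DM with `Y_crit = a + b·Tss` (mean spring–summer
temperature).

**ALAN variants** multiply the daily rate by the annual coefficient

    ALANin_i = exp(k · (ALAN_i − ALAN_max) / ALAN_max)

where `ALAN_i` is the year's radiance (nW cm⁻² sr⁻¹), `ALAN_max` the site's
series maximum, and `k` a fitted modulation strength. `k = 0` reproduces the
base model exactly; with `k < 0` the multiplier starts above 1 in dim early
years and decays to 1, so predicted DFS trends later as ALAN grows.

## Worked example

Simulate a city, generate observations from a CDD truth with a strong ALAN
effect (`k = −3`, 5-day observation noise), then calibrate base and ALAN
variants and compare:

```r
library(alanphen)

cfg  <- synthetic_config(n_sites = 3, years = 2001:2022, seed = 42)
site <- generate_site_dataset(cfg, 1)
truth_spec <- senescence_spec("CDD", alan_enabled = TRUE)
site <- simulate_observed_dfs(site, truth_spec,
                              c(T_th = 20, CDD_th = 300, k = -3),
                              noise_sd = 5, seed = 42)

base <- pso_calibrate(senescence_spec("CDD"), site,
                      config = pso_config(25, 60, restarts = 3), seed = 1)
alan <- pso_calibrate(truth_spec, site,
                      config = pso_config(25, 60, restarts = 3), seed = 1)
```

Printed results:

```
<calibration_result> CDD: objective 10.254 days over 22 years
    T_th   CDD_th
 21.2051 184.9708
<calibration_result> CDD_ALAN: objective 5.343 days over 22 years
    T_th   CDD_th        k
 19.0795 190.9143  -2.4347
```

The ALAN variant halves the fitting error (10.25 → 5.34 days, essentially the
injected noise floor) and recovers the sign and rough size of the true
modulation (`k ≈ −2.4` vs −3; the remaining gap reflects the usual
compensation among threshold parameters — the prediction surface, not the
raw parameter vector, is what is identifiable). Scoring both:

```r
eb <- evaluate_predictions(predict_dfs_site(senescence_spec("CDD"),
                                            base$best_params, site),
                           site$dfs_observed, k_params = 2)
ea <- evaluate_predictions(predict_dfs_site(truth_spec, alan$best_params,
                                            site),
                           site$dfs_observed, k_params = 3)
```

```
<evaluation_metrics> n=22 k=2  r=0.743 (p=7.49e-05)  RMSE=10.25  AIC=106.42
<evaluation_metrics> n=22 k=3  r=0.918 (p=1.77e-09)  RMSE=5.34  AIC=79.73
```

AIC drops by 27 despite the extra parameter: the ALAN term is decisively
preferred, as it should be on data generated with an ALAN effect. The
observed series itself trends later:

```r
ts <- theil_sen(site$dfs_observed, site$years)
# DFS trend: 1.714 days/yr (MK p = 1.99e-05)
```

## Layout

- `R/` — modules: `synthetic-data`, `astronomy`/`alan-processing`,
  `phenology-models`, `calibration-evaluation`, `sensitivity-trends`,
  `pipeline`.
- `vignettes/alan-senescence-methods.Rmd` — the methods vignette: model
  assumptions, parameter meanings and defaults, what the generator does and
  does not emulate, numerical choices, limitations.
- `inst/extdata/data-dictionary.md` — column names and units of the CSV
  bundle written by `write_site_dataset()` / `run_experiment()`.
- `inst/cli/alanphen.R` — `simulate` and `run-all` commands.
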