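# Data dictionary: site dataset CSV bundle

All tables are plain CSV, one row per record, written by
`write_site_dataset()` (and under `data/` by `run_experiment()`). Calendar
convention: fixed 365-day years, day-of-year (doy) 1-based, Feb 29 dropped.

## daily_temperature.csv

| column | type | units | description |
|---|---|---|---|
| site | string | – | site identifier (`site001`, …) |
| year | int | calendar year | |
| doy | int | 1–365 | day of year |
| temp | double | °C | daily mean air temperature |

## annual_series.csv

| column | type | units | description |
|---|---|---|---|
| site | string | – | |
| year | int | | |
| latitude | double | degrees | site latitude (constant per site) |
| alan | double | nW cm⁻² sr⁻¹ | annual mean ALAN radiance |
| lud | double | doy | leaf-unfolding date (spring phenology) |
| gdp | double | arbitrary currency | annual GDP |
| dfs_true | double | doy | noise-free model DFS (NA if never simulated or no crossing) |
| dfs_observed | double | doy | dfs_true + rounded Gaussian noise; NA = missing |

## monthly_climate.csv

| column | type | units | description |
|---|---|---|---|
| site | string | – | |
| year | int | | |
| month | int | 1–12 | calendar month |
| precip | double | mm | monthly precipitation |
| shortwave | double | W m⁻² | monthly mean shortwave radiation |

## Experiment outputs (`run_experiment()`)

- `model_comparison.csv`: model, n_sites, mean_r, sig_share (share of sites
  with Pearson p < 0.05), mean_rmse (days), mean_aic, config_hash.
- `sensitivity.csv`: site, preseason_length (months), partial_r, partial_p
  (temperature driver), dfs_trend (days yr⁻¹, Theil–Sen), dfs_trend_p
  (Mann–Kendall), config_hash.
- `projection.csv`: year, dfs (projected doy), config_hash.
- `manifest.json`: config hash and table list.
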