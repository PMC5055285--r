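# musselskill

Physiology-based skill assessment of intertidal body-temperature models.

## What this is for

Forecasting thermal stress in intertidal ectotherms (here the California
mussel *Mytilus californianus*) means choosing between models of very
different cost: air temperature as a direct proxy, a fixed solar-heating
regression (`T_body = T_air + 7.21×10⁻³ S`, with `S` shortwave irradiance in
W m⁻²), a site-fitted multiple regression on air temperature and solar, or a
steady-state biophysical heat budget. Conventional error metrics (bias, MAE,
RMSE) hide the differences that matter biologically, because an error of a
few degrees is harmless near the thermal optimum and decisive near the
lethal limit.

`musselskill` scores models the way weather forecasts are verified. Paired
daily maximum body temperatures (highest hourly average per site-local day,
over emersed low-tide hours only) are binned into seven thermal-performance
categories — low lethal (< 0 °C), low sub-lethal (0–10), low sub-optimal
(10–17), optimal (17–22), high sub-optimal (22–32), high sub-lethal (32–38),
high lethal (≥ 38 °C) — and each (forecast, observation) pairing is scored
with:

* per-category **hit rate** `H/(H+M)` and **false-alarm ratio** `FA/(H+FA)`
  (undefined ratios are reported as `NA`, never 0);
* multicategory **Heidke** and **Peirce** skill scores (skill relative to
  random forecasts; 1 = perfect, 0 = no skill);
* the **Gerrity** equitable skill score, built from an odds-ratio scoring
  matrix of the observed category frequencies so that every constant
  forecast scores exactly 0;
* bias / MAE / RMSE of the daily maxima (bias = predicted − observed);
* an **inter-logger baseline**: each logger at a site scored as a forecast
  of every other logger, bounding attainable model skill from above.

A seeded synthetic-data module generates environmental forcing (diurnal and
seasonal air temperature, clear-sky × autocorrelated-cloud solar, harmonic
tides, lognormal wind and waves) and multi-logger "robomussel" truth records
(heat-budget truth during emersion, SST during submersion, microsite
offsets, wave-splash resets, 2 °C instrument noise), so the whole pipeline
runs and is tested without any field data.

## Worked example

One synthetic summer (June–August, 10-min cadence) at an Oregon-like site
with three loggers, all four models:

```r
library(musselskill)

cfg <- experiment_config(
  sites     = list(site_config(n_loggers = 3)),
  generator = generator_config(seed = 1),
  models    = c("air_proxy", "elvin_gonor", "site_regression", "heat_budget"),
  seed      = 1)
res <- run_experiment(cfg)
res$site_reports[, c("model", "n_days", "bias", "mae", "rmse",
                     "heidke", "peirce", "gerrity")]
```

```
            model n_days   bias  mae rmse  heidke peirce gerrity
1       air_proxy    279 -4.460 4.48 4.91 0.00894 0.0165      NA
2     elvin_gonor    279 -0.896 1.31 1.58 0.18210 0.1116      NA
3 site_regression    138 -0.977 1.24 1.48 0.00000 0.0000      NA
4     heat_budget    279 -1.591 1.74 2.00 0.15146 0.1053      NA
```

Reading this: the air proxy runs ~4.5 °C cold on daily maxima — solar
heating pushes emersed body temperature far above air temperature — and has
essentially no categorical skill, while the solar regression and the heat
budget cut the error to 1–2 °C and gain real (if modest) skill. The site
regression is fitted on the first half of the season and scored
out-of-sample on the second half, hence its smaller `n_days`. Gerrity is
`NA` because a summer-only record never observes the cold categories, which
leaves its odds ratios undefined; `res$baseline` holds the inter-logger
benchmark and `res$tables` the 7×7 contingency tables behind every score.

Lower-level functions (`hourly_average()`, `fill_solar()`, `wave_runup()`,
`emersion_mask()`, `daily_max_pairs()`, `skill_report()`, ...) expose each
stage individually; `read_ndbc()` and `read_coops_tide()` parse standard
buoy and tide-gauge text files. A thin CLI with `generate` / `run` /
`verify` / `baseline` subcommands lives at `inst/cli/musselskill.R`.

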