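---
title: "Physiology-based skill assessment of intertidal body-temperature models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physiology-based skill assessment of intertidal body-temperature models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musselskill)
```

## The problem

Sessile intertidal ectotherms such as the California mussel *Mytilus
californianus* experience body temperatures that can differ from air
temperature by 10 °C or more, because solar radiation, wind, wave splash and
the timing of low tide all enter the animal's heat budget. Models used to
forecast thermal stress therefore range from trivially cheap (use air
temperature) to physically explicit (a full heat budget). The question this
package operationalises is not "which model has the lowest RMSE" but "which
model correctly predicts the *physiological category* a mussel's daily
maximum temperature falls into" — because an error of 3 °C near the optimum
is inconsequential while the same error at the lethal boundary decides
survival.

Body temperatures are binned into seven ordered thermal-performance
categories (lower-inclusive, upper-exclusive):

| index | label | range (°C) |
|---|---|---|
| 0 | low lethal | < 0 |
| 1 | low sub-lethal | 0–10 |
| 2 | low sub-optimal | 10–17 |
| 3 | optimal | 17–22 |
| 4 | high sub-optimal | 22–32 |
| 5 | high sub-lethal | 32–38 |
| 6 | high lethal | ≥ 38 |

The bounds come from the physiology of *M. californianus*: highest scope for
growth at 17–22 °C, heat-shock protein induction above 32 °C, and a median
lethal temperature of 38.2 °C, which is why 38.2 falls in the top bin. The
scheme is static: no acclimatization or thermal-performance plasticity is
modelled.

## Forecast/observation pairing

All scoring operates on **daily maxima**: the highest hourly-average
temperature within a site-local calendar day, computed separately for the
forecast and the observed series and only over hours when the logger is
emersed (exposed to air). Using the daily maximum frees models from having
to match the within-day temperature trajectory while preserving the
physiologically decisive quantity. Specifics:

* Hourly averages are arithmetic means of sub-hourly samples; exact
  on-the-hour point records are pair-averaged with the following point
  (`hourly_average()`, with a `point_values` switch because pair-averaging
  is not idempotent).
* Emersion is decided by still tide height plus a linear wave run-up proxy
  (`runup = coefficient × shore_slope × significant_wave_height`) compared
  against logger elevation above MLLW; ties count as submerged. The run-up
  treatment in the source field study is site-calibrated and unpublished, so
  the linear proxy keeps the coefficient exposed in configuration.
* Calendar days are site-local standard time (UTC plus a fixed offset, no
  daylight saving) — a "24 h period" is biologically a local day. Days with
  no emersed finite value on either side are dropped, not padded.
* Daytime-window solar products (09:00–16:00 local) are completed by
  `fill_solar()`: zero whenever solar elevation is non-positive, linear
  ramps between the window boundaries and the sunrise/sunset zero anchors.

## The four forecast models

1. **Air proxy** — body temperature equals air temperature.
2. **Fixed solar regression** — `T_body = T_air + 5.03 L` with insolation in
   Langleys min⁻¹, or equivalently `T_body = T_air + 7.21e-3 S` in W m⁻².
   The SI coefficient is used exactly as published; re-deriving it from the
   Langley form with 1 W m⁻² = 1.43 × 10⁻³ Langley min⁻¹ gives 7.19 × 10⁻³,
   a < 0.05 °C discrepancy at S = 1000 that the package preserves rather
   than "corrects".
3. **Site-fitted regression** — ordinary least squares of observed hourly
   body temperature on air temperature and solar irradiance over emersed
   hours (QR decomposition via `lm()`). An intercept is included by default
   with a switch to disable, since the original description is ambiguous.
   The pipeline fits on the chronological first half of days and scores the
   second half by default; in-sample fitting is available behind a flag
   because it inflates apparent skill.
4. **Steady-state heat budget** — the equilibrium temperature solving
   absorbed shortwave + long-wave exchange with sky and ground + convection
   + ground conduction = 0, with ground temperature equal to air
   temperature, sky temperature depressed a constant amount below air
   (constant-cloud assumption), evaporation neglected, and equilibrium
   assumed within the hour (mussel thermal time constants are 20–30 min).

### Heat-budget numerics and defaults

The flux balance is strictly decreasing in body temperature, so the root is
unique. It is found by a vectorised Newton iteration safeguarded by
bisection on the bracket `[T_air − 40, T_air + 60]` °C, to an absolute
residual below 10⁻⁶ W m⁻²; `stats::uniroot()` on the same balance serves as
an independent cross-check in the tests. Defaults (absorptivity 0.75,
emissivity 0.96, projected-area fraction 0.5, `h = 10 √wind` W m⁻² K⁻¹ with
wind floored at 0.1 m s⁻¹ as a free-convection floor, sky depression 15 K,
ground contact conductance 10 W m⁻² K⁻¹) are documented, physically
plausible values for a mid-size mussel on a horizontal bed — the published
model states its structure, not its constants, so these are this package's
own calibration choices.

## Verification statistics

With pairs binned into categories, a k × k contingency table (rows =
forecast, columns = observed) supports:

* per-category **hit rate** `n(F_i O_i) / n(O_i)` and **false-alarm ratio**
  `(n(F_i) − n(F_i O_i)) / n(F_i)`; both are reported as `NA` when their
  denominator is zero — rare hot categories genuinely produce undefined
  ratios, and coercing them to 0 would fabricate skill information;
* the multicategory **Heidke** and **Peirce** skill scores (proportion
  correct against marginal-matched, respectively observed-marginal, random
  forecasts);
* the **Gerrity** equitable score, built from odds ratios
  `a_i = (1 − Σ_{r≤i} p_r) / Σ_{r≤i} p_r` of the observed cumulative
  frequencies. The published rendering of the scoring-matrix formulas is
  typographically garbled, so the package implements the standard equitable
  construction and validates it two ways that do not depend on any
  transcription: every row of the scoring matrix satisfies
  `Σ_j p_j s_ij = 0` (any constant forecast scores exactly 0) and a perfect
  forecast scores exactly 1.

When a leading or trailing observed category is empty the Gerrity odds
ratios are undefined; `gerrity()` then errors with advice to collapse
categories, and the pipeline records `NA` for that pairing — consistent
with published per-site tables showing `NA` Gerrity entries at sites whose
cold categories were never observed. Undefined values propagate as `NA`
everywhere, never as zero.

Cross-site summary rows are unweighted means and sample (n − 1) standard
deviations of per-site values; sample rather than population SD is used
because it reproduces the published summary cells exactly.

The **inter-logger baseline** scores every ordered pair of loggers at a
site as (forecast, observation). It bounds attainable model skill from
above: if a model matches the inter-logger scores it is as useful as
deploying one more logger.

## The synthetic-data generator

No field data ship with the package; `generate_environment()` and
`generate_truth_loggers()` produce seeded records with the statistical
structure the analysis assumes:

* air temperature = mean + seasonal + diurnal sinusoids + AR(1) noise;
* shortwave = geometric clear-sky curve (declination/hour-angle elevation,
  1000 W m⁻² × sin(elevation) peak) × AR(1)-driven cloud transmission in
  [0.35, 1]; exactly zero when the sun is down;
* tide = mean level + configurable harmonic constituents (default M2 + K1 +
  S2-like, mean 1.2 m above MLLW, so a +1.5 m logger is emersed roughly half
  the time);
* wind and significant wave height are lognormal AR(1) processes;
* logger truth = steady-state heat budget during emersion (per-logger
  constant microsite offset added), SST during submersion, instantaneous
  splash resets to SST with probability `splash_rate` per emersed hour
  (inflated as the waterline approaches the logger), plus i.i.d. 2 °C
  instrument noise — the documented accuracy with which biomimetic loggers
  track live mussels.

All randomness comes from one seeded generator with a fixed draw order;
each logger uses the substream `seed + 7919 × logger_index`, and splash
uniforms are drawn regardless of the configured rate so that raising
`splash_rate` can only add splashes (a monotonicity the tests exploit).

The default season is one boreal summer (June–August) at an Oregon-like
site, 10-min cadence, three loggers: the heat-stress regime in which model
differences matter most. The microsite offset SD (2 °C) was calibrated once,
across eight seeds, so that the mean absolute inter-logger difference of
daily maxima sits mid-way through the 2–3 °C range reported for real
logger arrays; it was then frozen. What the generator does **not** emulate:
synoptic weather systems and heat waves (noise is AR(1), not fat-tailed),
fog, topographic shading, within-bed conduction, logger loss, and data gaps.
Passing tests therefore demonstrate that the pipeline's statistics behave
correctly on data with the assumed structure, not that any model is
accurate in the field.

## Problem sizes used in the tests

The shipped tests run one synthetic summer at hourly-to-10-min cadence with
two to five loggers (a few thousand paired hours, ~90 paired days per
logger), 10⁴ random contingency tables for the oracle-equivalence property,
and n = 5000 for regression parameter recovery — sizes chosen so the whole
suite completes in a few minutes while leaving every statistic's sampling
error far below the tested tolerances.

## Known limitations

* The steady-state model ignores thermal inertia; short splash-to-dry
  transitions are instantaneous in both truth and forecast.
* The linear run-up proxy is a placeholder for site-specific swash
  dynamics.
* Gerrity requires occupied cumulative observed categories; heavily
  one-sided seasons (e.g. summer-only records with no sub-10 °C maxima)
  yield `NA` rather than a score.
* Category bounds are fixed per scheme; no duration-weighted (degree-hour)
  stress metrics are provided.
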