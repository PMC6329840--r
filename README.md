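# heatrisk

Global heatwave risk under stabilized warming, for climate-impact and
risk-assessment work. **heatrisk** implements an end-to-end pipeline that
quantifies how heatwave *hazard*, population *exposure* and a development
based *vulnerability* proxy combine into a spatial risk index under 1.5 °C
and 2 °C warming levels and two socioeconomic pathways (SSP1, rapid
development; SSP4, inequality) — and ships a synthetic-data generator so
the whole chain is testable without multi-terabyte climate archives.

## The model

A heatwave is ≥ 3 consecutive days with daily maximum temperature above
the local calendar-day 90th-percentile threshold (31-day window over the
reference period). Its magnitude is the Heat Wave Magnitude Index daily
(HWMId): each day contributes max(0, (T_d − T25p)) / (T75p − T25p), the
anomaly over the 25th percentile of reference annual maxima scaled by
their interquartile range; the annual index is the largest event sum.

Hazard comes from extreme-value analysis of decadal block maxima: a GEV
fit by L-moments with shape constrained to ξ ≥ 0 (Gumbel/Fréchet), the
500-decade return level z₅₀₀ in the present climate, and the probability
of exceeding z₅₀₀ under each warmed state's fit. By construction the
present-decade chance is 1/500 = 0.2%. Profile-likelihood 95% intervals
and a parametric-bootstrap Anderson–Darling test accompany every fit.

Exposure and vulnerability are normalized through Johnson-system CDFs
fitted to present-period data — the log-normal branch (support [0, ∞))
for population density, the bounded branch pinned to (0, 1) for
1 − HDI — and the normalized risk index is

    IRI = (HW_hazard × Population_exposure × (1 − HDI)_vulnerability) × 100

with all factors in [0, 1]. Countries are classed by fixed HDI cutoffs
(low < 0.55, very high > 0.8), and population-exposure tables report, per
hazard-probability or IRI bin, the resident population as a percentage of
the present global population, with ensemble medians and ranges across
models and scenario-difference maps (2 °C − 1.5 °C, SSP4 − SSP1, worst −
best).

See `vignettes/heatwave-risk-methods.Rmd` for assumptions, parameter
defaults and numerical choices.

## Worked example

A one-model world on a 6×6 grid with 500-year climate states:

```r
library(heatrisk)

cfg <- run_config(seed = 7, n_models = 1, model_shapes = list(c(6, 6)),
                  years = 500, pop_shape = c(18, 18), n_countries = 9,
                  compute_ad = FALSE, compute_ci = TRUE,
                  compute_tx5x = FALSE, min_unique = 10)
bundle <- run_all(cfg)

hz <- bundle$models[[1]]$hazard
cell <- 15                               # a tropical low-variance cell
fit <- hz$fits$present[[cell]]
```

Inspecting that cell prints:

```
GEV fit (cell 15): loc 2.97 scale 1.82 shape 0.011 (lmom, 50 blocks)
HW500Y level: 14.64 (95% CI 11.86-31.73)
present exceedance: 0.2000%
hazard at this cell: 9.80% (1.5C), 65.28% (2C)
max normalized IRI, 2C/SSP4: 36.4%
population with IRI > 10% (2C/SSP4): 45.2% of present global
```

Reading: the present-climate GEV of decadal HWMId maxima at this cell puts
the 500-decade event at magnitude 14.6; by construction its present
per-decade chance is exactly 0.2%. Under +0.6 °C that same magnitude is
exceeded in 9.8% of decades, and under +1.1 °C in 65% — the hallmark
amplification of a warm, low-variability cell. Combining hazard with
normalized exposure and vulnerability, the worst scenario (2 °C, SSP4)
puts 45% of the present global population equivalent above an IRI of 10%.

## The analysis workflow

The numbered scripts under `analysis/` run the full study (two synthetic
climate models, all scenario combinations) and narrate what they find;
each writes tables and CSV rasters under `results/`:

```sh
Rscript analysis/01_simulate_world.R     # synthetic climate/population/HDI world
Rscript analysis/02_heatwave_hazard.R    # HWMId, GEV fits, hazard maps, GOF
Rscript analysis/03_normalize_risk.R     # Johnson fits, IRI fields
Rscript analysis/04_report.R             # ensemble tables, scenario differences
```

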