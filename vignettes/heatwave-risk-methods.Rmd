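---
title: "Heatwave hazard, exposure and the Illustrative Risk Index: methods"
author: "heatrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heatwave hazard, exposure and the Illustrative Risk Index: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind **heatrisk**, the
assumptions it makes, the parameters that matter, and the numerical and
design choices that a user should know before trusting (or extending) its
output.

## The risk model

Climate risk is treated as the interaction of three factors on a common
grid:

* **Hazard** — the per-decade probability that the Heat Wave Magnitude
  Index daily (HWMId) exceeds the magnitude of a very rare present-climate
  event;
* **Exposure** — population density, normalized to a (0, 1) score;
* **Vulnerability** — one minus the country-level Human Development Index
  (HDI), normalized the same way.

The normalized Illustrative Risk Index is the cell-wise product

$$\mathrm{IRI} = \left(\mathrm{HW}_{hazard} \times
  \mathrm{Population}_{exposure} \times (1-\mathrm{HDI})_{vulnerability}
  \right) \times 100,$$

with every factor in $[0,1]$, so $\mathrm{IRI} \in [0, 100]$ and vanishes
wherever any factor vanishes. In the present period the hazard factor is
$1/500 = 0.002$ by construction, so present IRI can never exceed 0.2. A
non-normalized variant (hazard × raw density × raw $1-\mathrm{HDI}$) is
also produced; its scale is dominated by the huge dynamic range of
population density, which is exactly why the normalized variant exists.
The index is illustrative: it is not calibrated to any dose–response
relation, and relative changes in any factor move it equally.

## Hazard: HWMId and constrained GEV block maxima

A heatwave is at least three consecutive days with daily maximum
temperature above the local calendar-day 90th-percentile threshold,
computed from a 31-day centred window pooled across the present-climate
reference years (windows wrap across the year boundary; the calendar has
365 days, no leap days). Each heatwave day contributes a magnitude
$(T_d - T_{25p})/(T_{75p} - T_{25p})$ when positive, where $T_{25p}$ and
$T_{75p}$ are quartiles of the reference-period *annual-maximum*
temperature series; the annual HWMId is the largest event sum of the year.
Scaling by the interquartile range makes magnitudes comparable across
climates with very different interannual variability — and is the reason
warm, low-variability regions respond so strongly to a fixed warming
increment. TX5x (annual maximum of the 5-day running mean of daily
maximum temperature) is computed alongside as a validation index.

Hazard is estimated by block maxima: decadal maxima of annual HWMId are
fitted with a Generalized Extreme Value distribution via L-moments
(unbiased probability-weighted moments and the standard rational
approximation for the shape). The shape is constrained to the
Gumbel/Fréchet branch ($\xi \ge 0$); when the unconstrained solution is
negative, the sample is re-fitted as a Gumbel distribution, which is the
exact limit of the constrained family — the fallback is continuous in the
sample. The headline event is the level with per-decade exceedance
probability $1/500$ in the present climate; its probability under a warmed
state is read from that state's own fit. **Return periods are counted in
decades (blocks), not years**: "HW500Y" denotes the level exceeded with
chance 0.2% in any one decade, which keeps the conventional label while
making the probability statement exact. Results are conditional on a
decade: no multi-decadal variability is modelled.

Two inferential companions: a 95% profile-likelihood confidence interval
for the return level (profiling the return level directly, nuisance
parameters re-optimized under $\xi \ge 0$, deviance cut at
$\chi^2_1(0.95)$), and a parametric-bootstrap Anderson–Darling
goodness-of-fit test (the statistic weights the tails, where the risk
lives; each bootstrap replicate is re-fitted before its statistic is
computed because the null parameters are estimated from the same sample;
200 replicates by default).

## Exposure and vulnerability: Johnson normalization

Both exposure and vulnerability are mapped to (0, 1) through a Johnson
distribution fitted to the **present-period** sample of the same variable;
projections are pushed through the present fit so all periods share one
scale. Population density uses the log-normal branch ($S_L$) with the
lower bound pinned at zero — its natural domain is $[0, \infty)$ and
zero-population cells sit exactly at score 0. The vulnerability proxy
$1-\mathrm{HDI}$ uses the bounded branch ($S_B$) with support pinned to
$(0, 1)$, the definitional range of the HDI; pinning guarantees that any
projected value, however far outside the present range, keeps a valid
score — the reason the bounded fit is constrained rather than free. With
both bounds pinned each branch has two free parameters $(\gamma, \delta)$,
and Gaussian maximum likelihood on the transformed scale ($\log x$,
$\mathrm{logit}\,x$) is the exact ML fit, so it is used directly rather
than a quantile-matching stage. A Kolmogorov–Smirnov test is the
goodness-of-fit arbiter; rejection flags the fit but does not fail it.

Ties are removed from the fitting sample only — never from the maps — so
two cells with equal raw values always receive identical scores. Future
population above the present range saturates at score 1.

## The synthetic world

All inputs are synthetic, generated to carry exactly the statistical
structure the analysis assumes:

* **Climate.** Daily Tmax = latitudinal baseline (28 °C at the equator,
  −12 °C to the domain edge at |60°|) + hemisphere-phased seasonal cycle
  (amplitude 10 °C) + state warming offset + within-year AR(1) noise
  (coefficient 0.7, reset at year boundaries so decadal maxima are
  exchangeable). The noise standard deviation is 1 °C inside the tropical
  band (|lat| < 20°) and 3 °C outside it: the contiguous low-variance band
  reproduces the high warming-to-noise ratio that amplifies changes in
  heat-extreme odds in the tropics. Warming offsets are +0.6 °C (1.5 °C
  world) and +1.1 °C (2 °C world) relative to the present state —
  approximate additional warming of the stabilization targets over a
  present decade.
* **Paired states.** The three climate states of a model share one noise
  realization and differ only by the constant offset (common random
  numbers). This was a deliberate design choice: it isolates the warming
  signal, makes the per-cell ordering of warmed-state hazards robust at
  desk-scale ensemble sizes, and guarantees the block-maxima series of a
  warmer state dominates the cooler one year by year. It also means
  states are not independent samples — acceptable because no test
  compares states as if they were.
* **Ensemble size.** 500 years per state (50 decadal blocks) by default.
  Real prescribed-SST ensembles of this kind run to 1000+ years; 500 keeps
  a full run in minutes on one CPU. Far-tail quantities are
  sensitive to this choice: with only 20 blocks the fitted shape is noisy
  enough that the per-cell ordering of exceedance probabilities across
  warming states can occasionally invert even though the underlying maxima
  dominate pointwise. At 50 blocks we observed no inversion across
  repeated seeds; users shrinking `years` below ~300 should expect
  far-tail orderings to become noisy before anything else does.
* **Population.** I.i.d. log-normal density (meanlog 4, sdlog 1.5,
  persons/km²) on a 36×36 native raster, with the southernmost 20% of
  latitude rows exactly zero — a contiguous uninhabited band that
  exercises the "population density greater than 0" masking rule even
  after conservative remapping. Future fields keep the present pattern
  and scale the global total to 120% (SSP1) and 140% (SSP4) of present,
  matching the end-of-century totals the two pathways imply.
* **Countries and HDI.** 36 contiguous rectangular countries; present HDI
  spread evenly over (0.45, 0.92) and shuffled across the map so each
  development class (low < 0.55, very high > 0.8, medium between — strict
  inequalities) is populated and decoupled from latitude. Future HDI
  closes 50% (SSP1) or 25% (SSP4) of each country's remaining headroom
  $1-\mathrm{HDI}$: monotone in time, ordered across pathways, always
  inside (0, 1).

What the generator does *not* emulate: trends within an ensemble state,
monsoon or any regional circulation, spatial autocorrelation of population
within the lognormal draw, sub-national HDI heterogeneity, coupled
ocean–atmosphere variability. Passing tests on this world demonstrate the
statistical machinery, not fidelity to any particular region of the real
world.

## Grids, remapping, aggregation

Population, HDI and country rasters live on a finer native grid and are
remapped onto each model grid by **first-order conservative** (area-overlap
weighted) averaging on the sphere; totals of density × area are conserved
to rounding. Second-order corrections need gradient estimation that adds
nothing on fields this smooth, so they were deliberately left out.
Countries are transferred by majority overlap area, ties broken toward the
lowest country id. People are counted as density × spherical cell area
(cosine-latitude weighting via increments of sin φ), and exposure tables
report population per hazard-probability or IRI bin as a percentage of the
present global population; bins are half-open with a closed final bin.
Across models, tables are summarized by per-bin median, minimum and
maximum.

## Numerical choices and degenerate inputs

* Percentiles everywhere (thresholds, reference quartiles) use linear
  interpolation between order statistics (type 7), so oracle tests can
  reproduce them exactly.
* Degenerate reference quartiles ($T_{75p} = T_{25p}$, e.g. constant
  input) define HWMId = 0 and flag the cell instead of dividing by zero.
* Cells whose block-maxima series is degenerate (all equal, typically
  all-zero HWMId) are masked from hazard and risk maps, not fitted.
* The L-moment fit requires at least 20 blocks; the Johnson fits at least
  30 unique values (both configurable).
* Profile-likelihood root-finding brackets geometrically outward from the
  ML estimate; non-convergence yields a missing interval and a flag, never
  an error. `alpha = 1` collapses the interval onto the point estimate.
* Missing cells are NA in memory and an empty field in the CSV rasters;
  they propagate through remapping (weights renormalized over non-missing
  contributors) and are excluded from fits, bins and class masks.
* All randomness flows from one integer seed; climate noise seeds are
  offset by the model index so models are independent while sharing the
  socioeconomic world. Re-running any configuration reproduces every
  artifact bit for bit.

## Problem sizes used by the tests

The test suite builds its worlds at the scale the property needs: 16-cell
grids and 200-year ensembles where only mechanics are asserted, and the
full default (8×8 or 9×9/12×12 grids, 500-year ensembles) where far-tail
orderings and distributional properties are on trial. The acceptance
study uses two models on 8×8 grids with 500-year states; the AD size
simulation uses 500 replicates of 100 blocks with 200 bootstrap draws
each; CI coverage uses 200 replicates of 100 blocks.

## Known limitations

* The IRI is an illustration of how vulnerability information changes the
  spatial pattern of risk, not a quantitative risk estimate; no
  dose–response relation is used.
* Hazard probabilities are per-decade and conditional on the simulated
  decade; they must not be read as multi-decadal return periods.
* Vulnerability is a single country-level number; within-country
  heterogeneity is absent by construction.
* The far tail (per-decade exceedance 0.002) is an extrapolation well
  beyond the largest observed block maximum; its absolute level inherits
  the usual fragility of 500-block return levels estimated from tens of
  blocks, which is why confidence intervals and the goodness-of-fit test
  ship with the point estimates.
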