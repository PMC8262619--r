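---
title: "Detecting water-quality trends with site-specific median anomalies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting water-quality trends with site-specific median anomalies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lakeanom)
```

## The estimation problem

Multi-site lake monitoring records are irregular longitudinal data: sites
enroll and drop out in different years, visit frequency differs by
parameter and by site, and nutrient and chlorophyll concentrations are
right-skewed with extreme values during bloom events. Two failure modes
dominate naive trend analysis of such data. *Pseudoreplication*: a site
visited weekly contributes an order of magnitude more rows than one
visited three times a season, so raw pooling weights sites by effort
rather than by information. *Staggered-enrollment bias*: when the set of
reporting sites changes over time, any systematic level difference between
early-joining and late-joining sites masquerades as a temporal trend.

The site-specific median anomaly estimator addresses both. Each site-year
is first collapsed to a single annual median; each site is then centred on
its own long-term median; only then are sites combined, with a cross-site
median per year. The yearly series is in the parameter's original units
(an anomaly of +0.5 µg/L means half a microgram above the site baselines),
and the estimator depends on each site-year only through its annual
median, which is what makes the pseudoreplication guard exact: replacing a
site-year's samples by any multiset with the same median changes nothing
downstream — a property the test suite checks directly.

Medians are used throughout instead of means because the concentration
variables are non-normal with outliers; the anomaly of a site untouched by
change is exactly zero in at least half its years, and single bloom years
cannot move the baseline.

## Assumptions

- Within a site, annual medians across years are treated as independent;
  no autocorrelation structure is modelled.
- Sites share a common *change* signal (the trend of interest) but not a
  common level; anomaly centring removes levels, not site-specific trends.
- The reference period (default: the whole analysis window) is long enough
  that the site median is a stable baseline. With an odd number of years
  and the default basis, each site's anomalies have median exactly zero by
  construction.
- Trends are monotone enough that an OLS slope on yearly medians is a
  meaningful summary; the estimator is not designed for cyclic or
  regime-shift dynamics.

## Eligibility screening

Sites enter the analysis per parameter only when their record can support
a long-term comparison:

| rule | default | purpose |
|---|---|---|
| analysis window | 1993–2016 (`uriww` preset), 1993–2013 (`lagos_ne`) | common time frame |
| months | May–October | growing season; winter access and ice preclude year-round sampling |
| depth | ≤ 2 m (`uriww`); disabled when depth unreported (`lagos_ne`) | surface/epilimnion samples only |
| seasonal coverage | ≥ 1 event in each of May–Jun, Jul–Aug, Sep–Oct | guards annual medians against seasonal aliasing |
| split-window presence | ≥ 1 event in each half of the record | site spans the record |
| minimum years | ≥ 10 qualifying years per parameter | enough years for a trend |
| minimum sites per year | 3 | yearly medians from ≥ 3 sites; years at exactly 3 flagged |

The seasonal-coverage rule is stated per year, which leaves open whether
it qualifies the *site* (at least one fully covered year) or each counted
*year*. The package defaults to the per-year reading (`coverage_mode =
"strict"`): a year contributes to the 10-year minimum, and its samples to
the anomaly series, only when all three bins are covered. The laxer
`"site"` mode is available for sensitivity analysis. Similarly, coverage
is assessed per parameter from that parameter's own sampling events; using
any parameter's events to define coverage would be an alternative reading,
not implemented as a mode because it couples parameters that may be
measured on different schedules.

## Trend fitting and the three-criterion classification

The yearly median anomaly is regressed on calendar year by unweighted OLS
(each retained year is one point; weighting by site count is available but
non-default, since the yearly median's precision grows slowly and unevenly
with site count). The slope's two-sided p-value uses the t distribution
with n − 2 df. A series with zero residual variance (all anomalies equal)
is reported with slope 0 and p = 1 rather than the 0/0 t statistic.

Classification deliberately avoids a single significance cut and instead
counts three lines of evidence:

1. **Statistical support**: p ≤ α, default α = 0.10. The default is an
   interpretation — it is the conventional level consistent with treating
   p = 0.065 as support and p = 0.14 as insufficient, the behaviour the
   rubric is calibrated to reproduce — and is configurable.
2. **Temporal pattern**: retained years are split at the midpoint of the
   observed year range; among years with nonzero median anomaly, an
   increasing pattern requires at least `pattern_fraction` (default 2/3)
   of positive-anomaly years to fall in the late half and of
   negative-anomaly years in the early half (each requirement applying
   only when that sign occurs). Years with anomaly exactly zero are
   neither high nor low and are excluded from the counts. The 2/3 default
   quantifies a qualitative "majority of high years late" judgement and is
   likewise configurable.
3. **Ecological magnitude**: |slope| ≥ a per-parameter threshold, each
   derived as a meaningful change spread over a century — temperature
   0.02 °C/yr (a 2 °C century warming limit), chlorophyll 0.035 µg/L/yr
   and TN 3.5 µg/L/yr and TP 0.1 µg/L/yr (the oligotrophic→mesotrophic
   limits 3.5, 350 and 10 µg/L over 100 yr), TN:TP 0.26 /yr (the gap
   between median molar ratios of nitrogen-limited, 35, and
   non-nitrogen-limited, 61, lakes over 100 yr). Equality attains the
   threshold. `threshold_derivations()` records each derivation.

≥ 2 criteria ⇒ trend, 1 ⇒ weak trend, 0 ⇒ no trend; direction follows the
slope's sign. On noisy, trend-free data individual criteria fire by
chance (the statistical one by design at rate α), so weak-trend labels on
null data are expected occasionally; the three-level scheme is a
communication device, not an error-rate guarantee. One concrete
false-positive mode: TN:TP has a magnitude threshold (0.26 /yr) small
relative to yearly ratio-median noise in small networks with sparse
nutrient schedules, so a chance drift can meet the statistical and
magnitude criteria together. The `trend-free networks` test bounds the
overall rate of full *trend* labels on null data at 10%.

## Derived TN:TP ratio

The molar ratio is computed per sampling event — TN and TP measured at
the same site, date and depth — as `(tn/tp) × 30.974/14.007`, the
atomic-weight ratio kept at full precision (2.2113…, conventionally
quoted as 2.21) to avoid compounding a display rounding across thousands
of ratios. Event-level pairing is the default because mixing dates within
a year would blur the ratio's within-season dynamics; site-year pairing is
available for sensitivity. Replicates within an event are collapsed to
medians first; events with TP = 0 yield no ratio and are counted.

## Numerical and convention choices

- **Medians**: midpoint of the two central order statistics for even
  counts, everywhere (annual, reference, yearly).
- **Quantiles**: linear interpolation between order statistics (type 7),
  so quartile bands are reproducible against the common default.
- **Trophic boundaries**: 3.5 / 9 / 24 µg/L chlorophyll for
  oligo-/meso-/eu-/hypereutrophic, boundaries belonging to the upper
  class. 3.5 is the standard oligotrophic–mesotrophic limit; 9 follows
  from the mesotrophic→eutrophic century rate of 0.055 µg/L/yr
  ((9 − 3.5)/100); 24 is a conventional hypereutrophic boundary. All are
  configurable.
- **Below-detection values**: retained as reported by default;
  `detection_limit_sensitivity()` reruns the pipeline without them and
  reports per-parameter classification agreement rather than suppressing
  disagreement.
- **Degenerate inputs**: < 3 years refuse to fit; < 4 years refuse the
  pattern criterion; a year surviving with exactly the minimum site count
  is flagged rather than dropped.

## What the generator emulates — and what it does not

`simulate_program()` produces long-format records from a network of
`n_sites` lakes: staggered enrollment (default: uniform over the first
decade) and optional dropout; May–October schedules per parameter
(defaults: 8 temperature visits per two-month bin ≈ weekly, 4 chlorophyll
≈ biweekly, 1 nutrient visit per bin = three per season); site levels
drawn per parameter (normal for temperature around 23 °C; lognormal for
chlorophyll, TN, TP around medians 3.5, 460 and 15 µg/L, matching the
skew of state-wide lake data where means sit well above medians); additive
normal noise for temperature and multiplicative lognormal noise for
concentrations; optional linear trends added to the site's noise-free
level; optional detection-limit flagging. Identical configuration and seed
give byte-identical output, and the noise-free series regress back to the
injected trend exactly (tested).

`three_lake_scenario()` encodes the minimal staggered-enrollment bias
demonstration: three lakes at levels 5/10/15 with the low lake observed
only in the early half and the high lake only in the late half, no
within-site trend. Its published form depends on an unpublished seed, so
the package treats it as a Monte Carlo property, not a value to match:
over replicates, raw yearly-mean OLS rejects the true no-trend null at
α = 0.05 in ≥ 90% of runs while the anomaly estimator rejects in ≤ 10% —
a contrast that holds across an order of magnitude of noise scales
(tested at σ = 0.3 and 3). Because only two lakes overlap in any year,
analyses of this scenario use a minimum of two sites per year; the
headline default remains three.

Not emulated: temporal autocorrelation and spatially correlated errors,
seasonal cycles within the growing season, measurement-method changes over
time, and non-linear or site-heterogeneous trends. Passing tests on this
generator therefore demonstrates correctness of the pipeline's algebra and
its robustness to enrollment and effort artifacts — not robustness to
autocorrelated or regime-shifting real-world series.

## Monte Carlo problem sizes

The test suite and acceptance script use: 500 replicates of the three-lake
scenario (rejection-rate contrast); 200–600 replicates of a 40-site ×
24-year balanced network with an injected 0.05 °C/yr warming trend for
bias and 95% CI coverage of the recovered slope — 600 in the test suite,
where the Monte Carlo standard error of a coverage proportion
(≈ 0.011 at 600 replicates) needs to resolve the 0.90 bound cleanly;
1000 replicates of 24-year null series for the type-I error of the slope
test; and randomized cohorts of up to 10 sites × 10 years for exact
equivalence against a brute-force loop-and-sort reimplementation.

## Known limitations

- OLS on yearly medians ignores serial dependence; in autocorrelated
  series the statistical criterion will be anticonservative.
- The yearly median anomaly has no closed-form variance here, so CI
  coverage of the slope is approximate (measured ≈ 92% at nominal 95% in
  the recovery setting).
- Anomaly centring removes site levels, not site-specific trend
  heterogeneity; a network where only late-enrolling sites are changing
  will still partially confound composition with change.
- The rubric's α and pattern fraction are interpretive defaults; both are
  configurable, and classifications near either boundary deserve a
  sensitivity check (`leave_year_out()`, `coverage_mode`,
  `reference_basis`, `weight_by_sites`).
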