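---
title: "An adjustable fetal weight standard for twins: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An adjustable fetal weight standard for twins: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinstandards)
```

## The model

Twin growth references built from a single population travel poorly: mean
birthweight differs by 100–150 g between race/ethnic groups in the US alone,
and applying one group's curves to another shifts SGA and LGA rates
mechanically. `twinstandards` instead treats the *shape* of fetal growth as
universal and only its *level* as population-specific.

The shape is the Hadlock median curve, an ultrasound-derived singleton
standard,

$$w(t) = \exp\!\left(0.578 + 0.332\,t - 0.00354\,t^2\right), \qquad
10 \le t \le 41 \text{ exact weeks},$$

which gives the unrounded reference value $w(37.5) = 3133.40\,$g at the
midpoint of 37 completed weeks. A population with mean twin birthweight
$\mathrm{MW}_{37}$ at 37 completed weeks receives the proportionality ratio
$r = \mathrm{MW}_{37} / w(37.5)$, and its adjusted median is $r\,w(t)$ at
every gestational age. Two assumptions close the model:

1. **Proportionality** — $r$ is constant across gestation: a population at
   86% of the reference at 37 weeks is also at 86% at 34 weeks.
2. **Constant coefficient of variation** — the SD of weight at any
   gestational age is a fixed fraction
   $\mathrm{CV} = \mathrm{SD}_{37}/\mathrm{MW}_{37}$ of the median there.

Percentiles then follow from normality of weight within a week:
$w_p(t) = r\,w(t)\,(1 + z_p \mathrm{CV})$, the z-score of an observed weight
is $(w - r\,w(t)) / (\mathrm{CV}\, r\, w(t))$, and SGA/LGA are the strict
tails below the 10th and above the 90th percentile (a weight exactly on a
cut point classifies AGA; classification is computed on the weight scale so
that boundary ties are exact rather than at the mercy of floating-point
round-trips through the z-scale).

We divide by the *unrounded* $w(37.5)$, not the rounded 3,133 g constant:
anchoring at exactly the Hadlock value then gives ratio 1 and reproduces the
reference curve bit-for-bit, while the printed constant is still recovered
on rounding.

## Parameters and defaults

| parameter | units | default | why |
|---|---|---|---|
| `mean_37`, `sd_37` | g | none (or bundled race anchors) | the anchoring point; both are required because the model's dispersion is the population's own CV, and no principled default CV exists when only a mean is known — supplying the Hadlock dispersion instead would silently mix two populations' variability, so the constructor insists on both |
| `ga_range` | exact weeks | 24–38.99 | the window over which the standard has been checked against observed weekly percentiles; configurable up to the Hadlock validity window 10–41 |
| percentile set | — | 3, 5, 10, 25, 50, 75, 90, 95, 97 | conventional chart percentiles |
| CV bound | — | `cv < 0.5` | beyond this the normal model places mass at negative weights well inside the chart percentiles; low requested percentiles that still go non-positive raise a degenerate-percentile error rather than clipping |

Gestational age bookkeeping: registries carry *completed* weeks, and week
$w$ is mapped to its interval midpoint $w + 0.5$ exact weeks (so 37
completed weeks anchors at 37.5); day-resolved input ($36$ weeks $+ 5$ days
$= 36.71$) bypasses the midpoint convention via `exact_weeks()`. The LMP/CE
reconciliation rule substitutes the clinical estimate when the two estimates
differ by *strictly more than* 2 weeks; ties at 2 keep LMP. Records with
only one estimate resolve to it — the alternative (exclusion) discards
usable births, and the `replaced` flag makes the fallback auditable.

The low-risk cascade defines "reliable gestational age and birthweight" as a
reconciled age within 17–47 completed weeks and a weight within 250–6,000 g
— standard natality plausibility screens, both configurable. Missing
covariates exclude conservatively and are reported in a separate column of
the filter report so substantive non-compliance is not inflated. The cascade
order affects only attribution: the retained set is the plain conjunction of
all criteria, which the tests verify directly.

Anchor estimation uses the sample SD ($n-1$ denominator) over records at
exactly the anchor completed week — not $\pm 1$ week — because the anchor is
defined as the mean of all births at 37 completed weeks. Group shares are
reported over the whole filtered cohort, matching how registry summary
tables present group sizes.

## The synthetic registry

The generator emulates the statistical structure the standard assumes, so
the full pipeline (reconcile → filter → anchor → curves) is testable with no
external data:

* race drawn from the bundled US cohort shares (70.9 / 16.8 / 7.8 / 2.5 /
  2.0%); the `other` group, for which no published anchor exists, defaults
  to the share-weighted average of the four named groups;
* true gestational age from a categorical distribution over completed weeks
  24–40, by default left-skewed with its mode at 37 — a realistic twin
  delivery-age profile (twins deliver a median of ~3 weeks before
  singletons);
* birthweight normal with mean $r_{\text{race}}\, w(\text{week} + 0.5)$ and
  SD $=$ CV $\times$ mean, truncated below at 250 g by redrawing (the same
  floor as the plausibility screen, so generator and filter agree);
* the clinical estimate equals the true completed week, while the LMP
  estimate is offset with probability `ga_error` (default 0.2) by a signed
  magnitude $1..6$ with geometric-decay mass (`error_decay` = 0.5). Only
  offsets beyond 2 weeks trigger replacement, so the expected replaced
  fraction is `ga_error` × P(|offset| > 2) ≈ 4.8% under the defaults. The
  real LMP error distribution in natality data is not characterised; this
  error model is explicitly synthetic, and its parameters are configuration,
  not constants;
* each low-risk criterion is violated independently with configurable
  probabilities (defaults 0.25 / 0.15 / 0.10 / 0.08 / 0.05 / 0.15),
  retaining roughly half of generated births — the same order of attrition
  as real low-risk selection.

What the generator deliberately does **not** model: within-pair birthweight
correlation (rows are independent twins), chorionicity, gestational-age-
dependent mortality selection, digit preference in recorded weights, or any
skewness in the weight distribution. Passing recovery tests therefore show
that the pipeline is a consistent estimator *under the model's own
assumptions*; they cannot show that real twin weights are normal with
constant CV.

## Empirical curves and comparison

Observed weekly percentiles use linear interpolation between order
statistics (the "type 7" convention — no single convention is universal, so
the choice is recorded in the table label), computed per completed week and
placed at the week midpoint so empirical rows align with model curves
evaluated under the same convention. Weeks with fewer than 20 records
(configurable) are omitted: tail quantiles are unstable in thin strata.
Model rows must be strictly increasing in percentile level; empirical rows
may tie (a week of identical weights returns that weight at every
percentile).

`compare_tables(a, b)` aligns rows by completed week, restricts to the
common percentile set, and reports per-percentile mean and maximum absolute
relative deviations of `b` from baseline `a`, with the week of the maximum.
Published comparisons of this kind are qualitative; these deviation metrics
are this package's own quantification. Overlay figures draw model curves
solid and empirical curves dashed, the convention of published growth-chart
overlays.

A diagnostic worth knowing: gestational-age dating errors destroy the
characteristic "gramophone" fan-out of percentile bands, inflating the
10th–90th band at early weeks where misdated heavier fetuses land. The test
suite reproduces this directionally by tabulating synthetic cohorts against
their *uncorrected* LMP weeks.

## Numerical choices

* All internal arithmetic is double precision; grams are rounded
  half-away-from-zero only when writing CSVs (base `round()` is
  half-to-even, which would write 2726 for 2726.5).
* Percentile z-values come from `qnorm()`, not tabulated constants, which is
  what makes the quantile round-trip and band-symmetry invariants hold to
  1e-9.
* Degenerate inputs fail loudly: both GA estimates missing, anchor strata
  with fewer than 2 records, zero-spread strata (flagged, since the CV is
  then unusable), non-positive weights, percentile requests outside (0,100).
* Stochastic commands refuse to run without an explicit seed; a fixed seed
  yields byte-identical registry CSVs.

## Validation scale

The test suite validates parameter recovery on a 50,000-birth synthetic
registry (every race's week-37 mean within 3 SE, shares within multinomial
3 SE), model-vs-empirical median agreement below 1% mean absolute deviation
at 5,000 births per week, and the dating-error band widening at 40,000
births — sizes chosen so sampling noise sits well inside the assertion
margins while the whole suite runs in a few seconds.

Sub-threshold LMP errors (offsets of 1–2 weeks survive reconciliation) leave
a small contamination bias in week-37 anchors — about −2.5 g under the
default error model, measured at 400,000 births — an order of magnitude
inside the 3 SE recovery margins at the sizes above, but worth remembering
if the generator's error rate is pushed far above its default.

## Known limitations

* The standard inherits the Hadlock shape; populations whose growth
  *trajectory* (not just level) differs are not captured by a single ratio.
* Constant CV understates the observed widening of the 10th–90th band in
  registry data at early weeks; the model band is narrower than observed
  tails there.
* No chorionicity-specific standard: monochorionic twins show wider limits,
  but no closed-form model is available to implement.
* Comparison against published external curves requires the user to supply
  those tables as CSV; none are bundled.
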