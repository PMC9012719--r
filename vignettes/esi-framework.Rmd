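---
title: "The Ecosystem Service Indicator: model, methods and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Ecosystem Service Indicator: model, methods and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esindicator)
```

## The problem

Water-resource managers need a single, communicable number that says
whether an ecosystem service — water supply, water-quality regulation,
sediment retention, flood protection — is meeting its demand, and that
degrades gracefully when data are scarce. `esindicator` scores
supply-demand delivery on a 0 (no delivery) to 100 (full delivery)
scale, the Ecosystem Service Indicator (ESI), from a table of
observations over *spatial units* (sub-basins, stations,
municipality-sectors) and *instances* (months of a series, annual maps,
static layers).

## The three dimensions

Failure is judged per instance against an *objective*: a sharp numeric
threshold with a direction (supply "must not fall short" of demand, or
a pressure "must not exceed" a standard), or a fuzzy objective where
stakeholders flag failures and rank their severity on a 1-10 scale. A
value exactly at a sharp threshold complies: its excursion would be
zero, and zero-gap "failures" are treated as artifacts, not signal.

Three dimensions summarise the failure pattern:

* **Scope** `F1 = 100 * (failing units) / (units)` — a unit fails if it
  misses its objective at least once.
* **Frequency** `F2 = 100 * (failing instances) / (monitored
  instances)`, all units pooled.
* **Amplitude** `F3` — how far failures deviate. Each failing instance
  contributes an excursion: `objective/value - 1` (shortfall),
  `value/objective - 1` (exceedance), or its fuzzy rank taken as-is.
  Two aggregates are used: the *normalized sum of excursions*
  `nse = sum(Ex) / (all monitored instances)`, which embeds frequency,
  and the *mean of excursions* `moe = sum(Ex) / (failing instances)`,
  a pure amplitude. Either is scaled onto \[0, 100) by the saturating
  map `100 x / (x + 1)`.

Because `moe` divides by a smaller (or equal) denominator,
`moe >= nse` always, and the moe-based F3 dominates the nse-based one.
Missing observations are excluded from every denominator; a unit with
no monitored instances drops out of the scope denominator too.

## Combination methods and evidence levels

* **M1** (the CCME water-quality-index combination):
  `ESI_3 = 100 - sqrt((F1^2 + F2^2 + F3^2)/3)` with the nse-based F3.
  Since nse already embeds frequency, M1 double-counts F2; it is kept
  as the reference formulation and defined only at evidence level 3.
* **M2**: `ESI_1 = 100 - F1`; `ESI_2 = 100 - sqrt(F1 * F2)`;
  `ESI_3 = 100 - sqrt(F1 * F3_nse)`. Level 3 pairs scope with the
  frequency-embedding amplitude, so F2 never enters twice.
* **M3**: levels 1-2 as M2; `ESI_3 = 100 - (F1 * F2 * F3_moe)^(1/3)`,
  each dimension entering exactly once.

The *evidence level* subscript records how much data the score used:
1 = scope only (a map suffices), 2 = scope + frequency (a time series
of pass/fail), 3 = all three dimensions (magnitudes or ranks). Levels
1-2 are identical for M2 and M3. Zero failures give exactly 100 at
every method and level; scores are clamped to \[0, 100\] after
floating-point combination.

```{r worked}
fx <- dongjiang_fixture()
esi_assess(fx$table, fx$objective)
```

The bundled worked example is a synthetic reconstruction of a drought
year in a six-municipality basin (17 municipality-sector units, twelve
monthly instances, reliability threshold 100%): nine units fail for
February-May at reliability 25.85. It pins down the framework's
published summary scores: F1 = 52.9, F2 = 17.6, nse-based F3 = 33.6.
The moe-based F3 evaluates to 74.15; the source table prints 74.2,
but moe is tied to nse through the counts (`moe = nse * 204/36`), which
makes 74.1 the value consistent with the printed 33.6 — a last-digit
rounding inconsistency we keep visible rather than tune away. For the
same reason report display uses one decimal, rounding half away from
zero, while all internal computation is unrounded.

## What the simulator emulates

`run_study()` generates reliability tables mimicking the worked
example's geometry (17 units x 12 instances, shortfall threshold 100)
under two controls drawn uniformly per table: *probability of failure*
(PoF), the per-cell Bernoulli chance of failing, and *range of failure*
(RoF), the maximum relative depth of a failure. Choices the generator
fixes, in the absence of a stated law:

* Compliant cells sit exactly at the threshold. Reliability cannot
  exceed 100%, and any at-or-above-threshold value yields identical
  scores, so the simplest choice is taken.
* Failing cells are uniform on `(threshold * (1 - RoF/100),
  threshold)` — the minimal-assumption reading of "sampling the
  probability distribution of possible input values" within the RoF
  bound.
* Failing values are rounded to one decimal (configurable). Rounding is
  what makes a zero-excursion "failure" — a draw that rounds back up to
  the threshold — reachable, as in real rounded monitoring data.
* Rounded values are floored at 0.1 (configurable, logged in the config
  echo) so the shortfall excursion never divides by a value near zero
  when RoF approaches 100.

Two discard rules mirror the study design: an all-pass table is kept
the first time and discarded on repetition (`discard_all_no_failure`
switches to discarding all of them), and a table whose Bernoulli
failures *all* rounded back to the threshold is discarded as an
artifact. Under the defaults the expected discard share is about
`1/205` (the chance an entire 204-cell table passes, integrated over
uniform PoF) — of order 1% of tables, consistent with the published
study's 129 of 10,000; the exact count depends on the unstated details
of the original generator and is not a calibration target. Likewise
the published subset means and correlation coefficients are treated as
generator-dependent observations: the analysis asserts their orderings
and the one robust magnitude (the OLS R-squared of F2 on PoF, which the
Bernoulli structure forces to ~0.99), not every printed decimal.

One RNG stream is seeded once and consumed in a documented order (per
table: PoF, RoF, one failure uniform per cell in unit-major order, then
one value uniform per failing cell), so a seed plus a config reproduces
a study bit for bit. Inside the study loop tables are scored by a
vectorised matrix path; a property test holds it exactly equal to the
public `esi_assess()` pipeline.

What the generator does *not* emulate: spatial or temporal correlation
of failures (droughts cluster months and neighbours), unit-specific
failure propensities, non-uniform failure depths, and unequal
monitoring effort. Passing the simulation tests therefore shows the
indicator's mathematical behaviour under independent stress, not its
behaviour on real basin data.

## Analysis choices

`summarize_study()` reports percentile tables, the Pearson correlation
matrix, designated OLS R-squared pairs, PoF-band subset statistics
(means and level-1/level-2 vs level-3 correlations for the default
bands 0-10, 20-30 and 40-50%), and rectangular binned grids of mean
level-3 scores over the PoF x RoF plane (a tabular stand-in for hexbin
displays — the statistic, not the graphic). Correlations and
regressions use retained tables only. Within a high-PoF band the
level-1 score can be constant in a small study (every unit fails in
almost every table), in which case the band correlation is reported as
`NA` rather than an error.

The study sizes used by the test suite (2,000 tables for module-level
checks, the full 10,000 for the study-level checks) were chosen so that
the orderings under test are resolvable above Monte-Carlo noise; the
finest ordering — level-2 vs level-1 agreement within a band, a gap of
~0.02 in r — is asserted only at full scale.

## Degenerate inputs and numerical notes

* Fuzzy ranks are accepted as reals in \[1, 10\]; the rank scale is
  ordinal in origin but nothing in the formulas requires integrality.
* `moe` over zero failures is defined as 0, so all-pass tables score
  100 without branching.
* Per-instance thresholds are supported; a scalar threshold broadcasts.
* Excursion of a non-positive value under a shortfall objective is an
  error pointing at the value-floor policy, not a silent clamp.
* Report JSON co-serialises rounded display values and raw doubles at
  17 significant digits (lossless round trip).

## Limitations

Scores aggregate a single service over one table; weighting several
services into a basin-level super-index, spatial-unit geometry, and
the construction of fuzzy ranks from multi-criteria surveys are out of
scope. The indicator is dimensionless and relative to its objective:
scores are comparable across services only insofar as the objectives
encode comparable ambitions.
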