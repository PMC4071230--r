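---
title: "Methods: FFQ scoring, screening, and two-instrument agreement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FFQ scoring, screening, and two-instrument agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffqtools)
```

## The measurement model

A semi-quantitative food frequency questionnaire (FFQ) asks, for each of a
fixed list of food items, how often the respondent consumed it over the
reference period and, for most items, which of a pictured set of portion
sizes corresponds to a usual eating occasion. `ffqtools` treats an
instrument as four registries: an ordered category list, a frequency scale,
one portion series per item, and a total map from items onto 35 standard
food groups.

Scoring is a linear model of intake. For item $i$ with chosen frequency
category $f_i$ and portion option $p_i$,

$$g_i = m_{f_i} \cdot s_{i,p_i} \quad \text{(grams/day)},$$

where $m_f$ is the per-day event multiplier of category $f$ and $s_{i,p}$
the gram weight of portion option $p$. Daily intake of nutrient $k$ is then

$$N_k = \sum_i g_i \, c_{ik} / 100,$$

with $c_{ik}$ the per-100 g composition value, and a food group's intake is
the sum of $g_i$ over its member items. Everything downstream (percent
energy, screening, agreement) consumes these quantities. The model is
deliberately linear: doubling every portion doubles every output, and group
totals conserve item mass; both properties are enforced by tests.

### Frequency multipliers

The nine-level scale from "never (<1 per month)" to "6+ per day" is scored
by the midpoint-of-range convention (events/day): never = 0, 1–3 per month
= $2/30.44$, once a week = $1/7$, 2–4 per week = $3/7$, 5–6 per week =
$5.5/7$, once a day = 1, 2–3 per day = 2.5, 4–5 per day = 4.5. The
open-ended top category is scored as exactly 6/day — the conservative
reading of an unbounded band; any other convention can be supplied in the
instrument file, which carries the multipliers explicitly.

### Percent energy

Percent of total energy uses the UK conversion factors of the McCance &
Widdowson tables: fat 9, protein 4, carbohydrate 3.75 (monosaccharide
equivalents), alcohol 7 kcal/g. Energy is read from the composition table's
energy field rather than recomputed from macronutrients, matching how
composition databases are actually used; `percent_energy(...,
energy_from_components = TRUE)` switches to the recomputed denominator, in
which case the four macronutrient shares total exactly 100%. A zero-energy
record has *undefined* %TE (`NA`), never 0.

## Deriving composition and portion series from survey records

The derivation module reproduces the national-consumption-survey procedure
used to parameterize such instruments:

* **Composition.** For each item, the mapped survey foods are ranked by how
  frequently they were consumed and the per-100 g composition of the item
  is the unweighted mean over the top $k = 3$. "Most frequently consumed"
  is interpreted as the number of consumption records (an
  occurrence count); ranking by distinct consumers is available as an
  option since survey practice varies. Ties break lexicographically by food
  code so the selection is reproducible.
* **Portion series.** Anchors are the 25th/50th/75th percentiles of daily
  intake (amounts summed per respondent first; a per-occasion switch
  exists), computed by linear interpolation between order statistics —
  `stats::quantile()` type 7, stated here because the percentile estimator
  is otherwise underdetermined and the test oracles depend on it. The
  7-option series brackets the anchors:
  $\{0.5 p_{25},\ p_{25},\ \tfrac{p_{25}+p_{50}}{2},\ p_{50},\
  \tfrac{p_{50}+p_{75}}{2},\ p_{75},\ 1.5 p_{75}\}$, rounded to 0.1 g. If
  rounding collapses neighbours — in the limit, all amounts equal $c$ — the
  series falls back to the multiplicative grid
  $\{0.5, 0.75, 0.9, 1, 1.1, 1.25, 1.5\} \cdot p_{50}$, so a valid 7-option
  nondecreasing series is always returned.

## Energy-plausibility screening

Basal metabolic rate comes from the published Henry weight-and-height
equations, shipped as a versioned coefficient file
(`inst/extdata/henry_coefficients.csv`; MJ/day converted to kcal/day by
239.005736). Age bands are lower-inclusive — age 30 uses the 30–60
coefficients — and ages below the lowest band (18 y) are an error, not an
extrapolation, since the packaged table is adult-only.

The under-reporting rule is a one-sided floor: the lowest plausible energy
requirement is $1.1 \times \mathrm{BMR}$, and a reported intake *strictly*
below it flags the respondent. Intake exactly at the floor is not flagged.
The cohort filters mirror a paired-administration design: respondents with
more than 28 days (strictly; 28 is retained) between the two completion
dates are excluded, as are respondents above 4500 kcal/day (strictly; 4500
is retained) on the online instrument — the threshold is configurable and
can be applied to either or both instruments. Missing dates exclude with an
explicit `incomplete` reason rather than silently dropping the respondent,
and the filter is idempotent.

## Agreement statistics

* **Bland–Altman.** Differences are reference-minus-candidate ($x - y$),
  limits of agreement are the literal mean $\pm\, 2\,\mathrm{SD}$ (the
  convention of the FFQ-comparison literature, not 1.96; `k_sd` is a
  parameter), SD uses the $n-1$ denominator, and the methods are declared
  comparable when strictly more than 95% of differences lie within the
  limits. Zero-variance differences collapse the limits onto the mean with
  100% within — a documented fixed point, not an error.
* **Cross-classification.** Values are ranked with average ranks and cut at
  ranks $n/4, n/2, 3n/4$ (upper-inclusive). Because text conventions for
  "disagreement" differ, four mutually exclusive bins
  $|\Delta q| \in \{0,1,2,3\}$ are reported alongside the combined
  $|\Delta q| \ge 2$ figure. The procedure is rank-based and therefore
  invariant to strictly monotone transforms; ties too heavy to form the
  strata are an error naming the variable (the orchestrator records such
  variables as `NA` with a note instead of failing the whole report).
* **Correlations** wrap `stats::cor.test` (Spearman by default for food
  groups; both kinds available — published comparisons mark only some
  nutrients as Pearson, so the kind is configuration, not hard-coded).
* **Adjusted comparison.** Nutrient differences between methods are tested
  by OLS on the stacked table, `intake ~ method + energy` plus optional
  center/gender/randomization covariates, with rows treated as independent
  observations — the convention of the validation literature this mirrors;
  a paired-aware variant was considered and deliberately left out of the
  default because it changes the estimand. Method-by-covariate interactions
  are tested one at a time against the main-effects model. A zero-variance
  covariate is dropped with a message (this is what makes the model reduce
  exactly to the two-sample mean difference when energy is constant);
  genuine collinearity among informative columns errors, naming the aliased
  terms. Energy itself is never energy-adjusted.
* **Food-group t tests** default to Welch's unequal-variance form, with the
  pooled-variance test as an option.

`compare_instruments()` orchestrates the full battery over the nutrient
panel (24 nutrients + 6 %TE fields) and the 35 food groups, aligns
respondents (misalignment errors with the symmetric id difference), and
adds the under-reporter concordance when demographics are supplied.

## The synthetic cohort generator

The generator exists so every module is testable with known ground truth
and no survey data. Its latent model:

1. Each respondent consumes each item with probability 0.8; consumed items
   get lognormal true grams/day centred on half the medium portion per day,
   then each respondent's profile is rescaled so true daily energy is
   lognormal with median 2300 kcal ($\sigma_{\log} = 0.22$) — magnitudes a
   dietary survey of healthy adults would call typical.
2. Method $m$ observes $b_m \times \text{truth} \times e^{\varepsilon}$,
   $\varepsilon \sim N(0, \sigma^2)$ with $\sigma = 0.25$ by default
   ($b_m$ is the method's multiplicative reporting bias), and reports the
   frequency–portion pair whose product is nearest the observation in log
   space, ties to the lower option. Quantization error is therefore bounded
   by half the log-gap between adjacent representable intakes.
3. Under-reporting is controlled exactly: a designated fraction of
   respondents is rescaled to $0.85 \times$ their EER floor (the 15% margin
   absorbs quantization and noise so both instruments flag them), and all
   others are kept at or above $1.25 \times$ the floor. With two identical
   item lists the flagged fraction equals the designed fraction almost
   surely; with item lists of different lengths the narrower instrument
   scores lower energy and flags more respondents — the generator
   reproduces, rather than hides, that structural asymmetry.
4. Demographics are sex-balanced, age uniform 18–60, with sex-specific
   weight/height normals of plausible adult magnitude; completion gaps are
   Poisson (mean 7 d) with random sign.

What the generator does *not* emulate: food-level dietary realism,
correlations between items, seasonal effects, or any fitting to a real
cohort's distributions. Passing recovery tests therefore demonstrates that
the pipeline's statistics faithfully measure what was injected — not that
the instrument itself is valid for any real population.

## Packaged instrument fixtures

`food4me_instrument()` (157 items, 11 categories, 9-level scale, 7-option
series) and `epic_norfolk_instrument()` (the 130-item base list; the two
differ by exactly 27 items) carry the documented structure of the
online/printed instrument pair. Item *names* are placeholders flagged
`fixture = TRUE`, because the published material enumerates counts and
categories, not the full item text; per-category counts are a documented
allocation consistent with those totals. The 35-group map is total over
both fixtures and uses all 35 groups in each.

## Numerical choices and problem sizes

Quantile type 7 everywhere; portion rounding to 0.1 g; sample SD with
$n-1$; strict inequalities at every screening boundary; lexicographic
tie-breaks in derivation; lower-option tie-breaks in quantization. The test
suite runs its simulation checks at $n = 1000$ (bias recovery, injected
$b_B = 1.3$ recovered within 5 percentage points of ratio), $n = 2000$
(designed under-reporter fraction 0.2 recovered within $\pm 0.03$),
$n = 10{,}000$ (normal-theory ~95.4% within mean $\pm$ 2 SD) and
$n = 100{,}000$ (25% exact-quartile-agreement independence null within
$\pm 0.5$) — sizes at which Monte-Carlo error is comfortably inside each
tolerance while the whole suite stays interactive.

## Known limitations

* The adjusted comparison ignores the within-respondent pairing (by
  design, to match standard practice); its p-values are anticonservative
  when within-person correlation is high.
* The Henry table is adult-only; adolescent bands would need a table
  extension.
* The packaged fixtures carry instrument *structure*, not real item text or
  a real composition database; absolute intakes from them are meaningful
  only relative to the composition table supplied.
* Dietary-habit add-ons (added salt, fried food, supplements) are carried
  as metadata and never scored.
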