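---
title: "Methods: scoring, profiling and burden attribution of climate-sensitive pathogens"
author: "climsens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, profiling and burden attribution of climate-sensitive pathogens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(climsens)
```

## The assessment model

`climsens` operationalises a semi-quantitative literature-evidence risk
assessment. The unit of information is an *evidence record*: one literature
finding linking a pathogen to a climate driver with a signed strength score.
The analysis makes three structural assumptions, each deliberate and each a
limitation:

* **Records are exchangeable.** Every record contributes one score; there is
  no weighting by study design, venue or recency. The score itself is the
  only carrier of evidence strength.
* **The median is the summary.** Per (pathogen, driver), the sample median
  of all scores decides sensitivity. The median resists a single extreme
  claim in either direction; the strict rule `median > 0` means that evenly
  contradicted evidence (e.g. scores 60 and −60, median 0) does *not* count
  as sensitivity. Pairs with no records at all are kept distinct from pairs
  with non-positive medians in outputs, but both count as "not sensitive"
  downstream.
* **Drivers live at the 11-set level.** The underlying literature search
  uses a large vocabulary of climate terms, but every statistic operates on
  eleven driver sets with a fixed primary/secondary classification: primary
  drivers are climate variables themselves (climate change, oscillations,
  extreme weather events, moisture, rainfall, temperature, wind), secondary
  drivers are combinations, consequences or proxies (altitude, vegetation,
  particulate matter, salinity). The term→set mapping is therefore out of
  scope here; the 11-set vocabulary ships as a packaged CSV and can be
  overridden by YAML (`driver_vocabulary()`) for regrouping experiments.
  Secondary-driver evidence deserves caution in interpretation: altitude, in
  particular, can proxy socio-demographic gradients as much as climate.

## Tunable parameters

| Parameter | Default | Units / scale | Why |
|---|---|---|---|
| rubric grid | `c(5, 20, 40, 60, 80)` ± | dimensionless evidence strength | every published median is reachable as a grid value or midpoint of two |
| positivity rule | `median > 0`, strict | — | the binary split is positive vs lacking positive evidence |
| all-cause DALY total | 2,490,385 | thousand DALYs, 2010 | denominator of relative impacts |
| logistic convergence | IRLS, `epsilon 1e-8`, 100 iterations | — | coefficient changes below tolerance end iteration |
| selection rule | enter p < 0.05 univariable, drop p ≥ 0.05 | — | fixed, documented multivariable procedure |
| borderline band | p ∈ [0.05, 0.10) | — | flagged, not treated as significant |

Statistical conventions, chosen once: Pearson χ² is computed **without**
continuity correction, because the φ effect size √(χ²/N) is only consistent
with the uncorrected statistic. Odds-ratio and logistic intervals are Wald
(symmetric on the log scale); no profile-likelihood or Firth option exists in
this version, so complete separation is detected (a fitted probability pinned
at 0/1, checked directly since `glm` does not always warn on small data) and
flagged with a classed warning plus `diverging_ci = TRUE` rather than
silently reported. H-index quartiles cut at the empirical 25/50/75
percentiles with ties assigned to the lower quartile, so equal H-indices can
never straddle a boundary. Pathogens with unknown host class are removed
listwise from zoonotic models only. No multiple-testing adjustment is
applied anywhere, matching the assessment style the package implements.

The rainfall and climate-change emergence models are fitted as two separate
multivariable models (each with its own H-index quartile block), not
jointly: each question is "does this driver raise the odds of being classed
emerging, H-index held fixed", and the two drivers overlap in few pathogens.

## What the synthetic generator emulates

`simulate_study()` exists so that every stage is testable at realistic scale
and so that configured effect sizes are recoverable. Its defaults describe a
cohort of 157 pathogens with the marginal structure of a European
high-impact assessment:

* taxon mix dominated by bacteria and viruses, with small helminth (6) and
  protozoan (7) contingents;
* route propensities ordered direct contact > foodborne > airborne > fomite
  > waterborne > sexual > vector-borne > soilborne, every pathogen keeping
  at least one route;
* latent (pathogen, driver) sensitivity Bernoulli with probability
  `driver_base_rate × driver_weight[d] × max(route_driver_boost[routes])`.
  The per-driver weights make moisture and rainfall the most frequent
  drivers and oscillations/vegetation the rarest; the route boosts order
  vector-borne > soilborne > waterborne > foodborne > contact. With the
  default base rate 0.06 the closed-form expected latent sensitive fraction
  (`expected_sensitive_fraction()`, exact by enumeration over the 2⁸ route
  subsets) is 0.637, and the observed median-positive fraction lands near
  0.62–0.63 — about 99 of 157 pathogens;
* observed evidence is noisy: sensitive pairs draw ≥ 1 records (Poisson,
  floored) with 12% negative scores, insensitive pairs occasionally draw
  noise records (rate 0.04) that are 85% negative — so observed positivity
  is a *measurement* of the latent truth, and the attribute table carries
  the truth columns (`sensitive_truth`, `n_drivers_truth`) that
  parameter-recovery tests regress on;
* the zoonotic flag is assigned so the latent any-driver log-odds difference
  equals `log(zoonotic_sensitivity_or)` (default 6); emergence depends on
  latent rainfall sensitivity (OR 2.75) and top-quartile H-index (OR 3.7);
  reporting-country counts are Poisson with mean 8 + 1.1 per latent driver,
  truncated at 34 countries.

What it does **not** emulate: publication behaviour (no citation dynamics or
H-index growth — H-indices are plain lognormal draws), correlation between
taxa and routes, driver co-occurrence beyond what shared route boosts
induce, and any climate-change projection. Tests passing on synthetic data
therefore certify the machinery — aggregation, counting, model fitting,
recovery of built-in effects, null calibration — not the epidemiological
truth of any real cohort.

## Numerical and degenerate-input choices

* Medians of even-sized score sets are the midpoint of the two middle order
  statistics (so grid medians like 22.5 arise naturally).
* Percentages are never stored, only derived, and rounded (1 dp for shares,
  2 dp for relative impacts) at display time only.
* 2×2 tables with a zero row/column margin raise a degenerate-table error
  rather than returning χ² = NaN; odds ratios with a zero cell error unless
  Haldane–Anscombe continuity (+0.5 on all cells) is requested — the
  cohort-battery odds ratios enable it, since a strong true effect can empty
  a cell in a 157-pathogen cohort.
* Driver-frequency and co-occurrence rankings break ties alphabetically, so
  reports are stable across platforms.
* All simulation randomness flows from one seed through a private RNG scope
  that restores the caller's `.Random.seed`; identical configs give
  byte-identical tables.
* An inestimable battery component (e.g. a driver that no pathogen in a
  small cohort carries) is reported as absent rather than failing the other
  models.

## Problem sizes in the test suite

The suite checks the median aggregator against a brute-force oracle on 10⁴
random multisets; the logistic/odds-ratio identity on 100 random 2×2 tables
(to 10⁻⁶); recovery of a configured zoonotic-sensitivity OR of 3 at
n = 5000 over 200 seeded replicates (Wald coverage ≥ 90%); and null
calibration over 100 replicate cohorts of 157 with all generator effects
switched off (every interval covering its null ≥ 90% of the time). These
sizes keep the full suite around a minute on one core while leaving the
Monte-Carlo margins comfortable.

## Known limitations

* Direction of association is not modelled: the assessment identifies
  sensitivity, not whether warming increases or decreases a disease, and
  non-linear or co-dependent driver relationships are outside its reach.
* The evidence model ignores source quality and directness of driver action;
  the record schema reserves a free-text tag for directness, but no
  computation uses it.
* Wald intervals undercover for very sparse cells; with this cohort size
  that mainly affects the climate-change emergence model, whose borderline
  behaviour is flagged rather than resolved.
* The burden stage consumes published DALYs as-is; no uncertainty in the
  GBD estimates is propagated.
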