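---
title: "Methods: GP-practice archetype discovery and its synthetic test-bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GP-practice archetype discovery and its synthetic test-bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the clustering
model and its assumptions, the parameters that matter, what the synthetic
generator does and does not emulate, and the design decisions taken where
the design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. The classification model

Each GP practice is summarised over a 12-month window by six features
(`feature_names()`): the count of distinct dispensing pharmacies, annual
dispensed items per registered patient, the item-weighted median and
item-weighted population SD of the practice-to-pharmacy distance (km,
straight-line on planar easting/northing), the local population density
(persons/km²), and the mean registered list size. Distance is a proxy for
the geographic sphere of influence of the practice: no patient-level
geography is available, so the pharmacies that dispense a practice's
prescriptions stand in for where its patients live and work.

Assumptions worth making explicit:

* **Planar geometry.** Distances are Euclidean on grid metres divided by
  1000. At regional scale the error against great-circle distance is
  negligible, and published practice/pharmacy coordinates come on exactly
  this grid. No reprojection, no postcode parsing: coordinates arrive as a
  lookup table (`location_code,easting_m,northing_m`).
* **Item weighting.** Each dispensed item counts as one journey, so the
  median/SD distance features weight each pharmacy by its items. The
  alternative (one vote per practice–pharmacy–month row) would let a
  pharmacy dispensing 3 items count as much as one dispensing 30,000.
* **Annualisation.** `items_per_patient` is the window total divided by the
  mean monthly list size — items per patient *per year*. Values around
  250–270 are on the per-year scale of the published centroid table; the
  monthly phrasing that sometimes accompanies this feature describes data
  granularity, not the feature's units.
* **Whole-period presence.** Practices with dispensing activity in fewer
  than all 12 window months are excluded (openings/closures are out of
  scope); the filter's before/after counts are logged.

Features are z-scored (sample SD) before clustering because they live on
scales four orders of magnitude apart; k-means on raw units would cluster
on population density alone. Standardisation fails loudly on a constant
column rather than silently dividing by zero.

## 2. Clustering and k selection

`fit_kmeans()` implements Lloyd iterations with k-means++ seeding,
`n_init = 50` restarts, `max_iter = 300`, and convergence when no centroid
moves more than `1e-6` (standardised units). The restart count and
tolerance are deliberate overkill for n ≈ 333 practices: the suite verifies
that the solver attains the *global* optimum on every random instance with
n ≤ 8, k = 2 against a brute-force partition enumeration, and empty
clusters are reseeded at the farthest point rather than silently dropped.
Cluster indices are canonicalised by first-member row so output is
invariant to restart order.

Two selectors for k are reported side by side:

* **Elbow** (`select_k_elbow`): the visual elbow is operationalised as the
  interior k maximising the second-order difference
  `inertia(k−1) − 2·inertia(k) + inertia(k+1)` over k = 1..10, ties broken
  toward smaller k. The inertia curve must be non-increasing; a restart
  artefact violating that triggers one refit at 5× restarts, then an error.
* **Silhouette** (`select_k_silhouette`): k maximising the mean silhouette
  width (Euclidean, via `cluster::silhouette`), ties toward smaller k.

When the two disagree the silhouette wins, because the elbow's
second-difference rule is a discretisation of a visual judgement while the
silhouette is a bona-fide internal validity index; both values are always
recorded in `k_selection.csv`.

With k = 2, labelling is mechanical: the cluster whose de-standardised
population-density centroid is larger is **Metropolitan** (exact ties — a
measure-zero event — break by the larger pharmacy-count centroid). The
centroid report pairs each de-standardised centroid with the sample SD of
that feature among the cluster's members; the ± values in the published
centroid table are read as exactly these within-cluster SDs. That reading
is a choice — standard errors or month-to-month variability are also
conceivable — and it propagates into the generator below; the
items-per-patient SDs (5.8 and 3.4) are implausibly tight for an
across-practice SD, which makes the two archetypes extremely well separated
on that axis. The label-recovery acceptance results should be interpreted
with that caveat: they certify the pipeline, not the difficulty of the
original clustering problem.

PCA (`pca_project`) is used for visualisation only; components are
sign-fixed (largest-magnitude loading positive) so plots are reproducible
across BLAS implementations.

## 3. Prescribing comparison

Rows lacking BNF chapter or section are tagged chapter 99 and excluded
(`clean_bnf`), with the excluded fraction logged. Cluster series divide
*pooled* items by *pooled* registered patients per month — not the mean of
per-practice ratios — so small practices cannot dominate. Chapters are
ranked by the RMSE between the two clusters' monthly series; within the top
chapter, sections are ranked the same way. Section-level inference uses
per-practice *annual* items-per-patient observations (one observation per
practice, avoiding month-level pseudo-replication) in Welch's
unequal-variance t-test; practices with no rows in a section enter as true
zeros. Raw p values are reported alongside Benjamini–Hochberg adjusted
ones, with `alpha = 0.05` as the conventional flag threshold.

## 4. Deprivation

Ward deprivation ranks must form a permutation of 1..W. The default
convention is `rank 1 = most deprived` (the usual multiple-deprivation
convention) and is configurable. Quartiles are balanced (sizes differ by at
most 1, remainder to the lower quartile numbers), Q1 least deprived.
"Share in the most-deprived half" is Q3 + Q4 — the only reading consistent
with the published Metropolitan figure. The published overall figure for
the Non-Metropolitan most-deprived-half share is arithmetically
inconsistent with every pair of its own table entries and is deliberately
not reproduced.

## 5. The synthetic cohort: what it emulates

`default_archetypes()` encodes the stated world: 90 Metropolitan and 243
Non-Metropolitan practices; six feature means/SDs from the published
centroid table; deprivation-quartile mixes from the published quartile
rows; pharmacy-dispersion targets 26.2 km and 40.4 km; 0.24% of prescribing
rows stripped of BNF codes.

**Feature level** (`sample_feature_level`) draws the six features
independently per practice from the archetype Gaussians, truncated to
physical bounds (integer pharmacy counts ≥ 1, distances ≥ 0.1 km, distance
SD ≥ 5% of the median, density ≥ 1, list size ≥ 100). Feature correlations
are *not* modelled — no correlation information is published — so the
feature cloud is axis-aligned in a way real practices are not.

**Record level** (`generate_records`) realises all five input tables. The
geometric core: a practice's P pharmacies sit at uniform angles and
log-normal radii. A log-normal with median m and SD s has
`sdlog² = log((1 + √(1+4(s/m)²))/2)`; that shape is scaled by a factor
`s*` calibrated (`calibrate_radial_scale`: Monte-Carlo mean pairwise
distance, bisection, 2% tolerance) so the cloud's mean pairwise distance
hits the archetype dispersion target. Items are then allocated to
pharmacies multinomially with distance-decay weights `w ∝ r^(−β)`,
`β = log(s*)/sdlog²`. Exponential tilting of a log-normal by `r^(−β)`
shifts only its log-mean, so the *item-weighted* distance distribution
drops back exactly onto the practice's sampled median/SD targets while the
*unweighted* pharmacy cloud keeps the calibrated dispersion. This is the
same mechanism that reconciles the published figures themselves (a 4.6 km
weighted median distance alongside 26.2 km mean pharmacy separation can
only coexist if patients favour nearby pharmacies), and choosing it was
forced: uniform allocation cannot satisfy the median, SD, and dispersion
constraints simultaneously. Two pragmatic guards: a 2% uniform floor is
mixed into the weights so every pharmacy dispenses something (keeping the
extracted pharmacy count exactly P), and radii are rescaled per practice so
the realised weighted median equals its target (removing finite-P sampling
noise; the tests show this costs the dispersion mean about 2%, well inside
its 5% acceptance band).

Monthly item totals are Poisson around the annualised target rate with ±5%
uniform month effects (no published within-practice variability exists;
this is a modelling choice). Quarterly list sizes get a 0.3% jitter and are
forward-filled over their three months. Chapter mixes give chapter 4 a
0.20 vs 0.16 share with the excess carried by section 7 (60%) and section
3 (40%); other chapters (1–13 are generated) share the remainder equally up
to a fixed ±10% wobble, and small opposing section tilts make sections 6
and 9 higher in Non-Metropolitan practices and section 10 equal in absolute
terms. These mixes are *qualitative inventions* engineered to reproduce
ordinal findings — which chapter and sections dominate the between-cluster
difference, which section stays non-significant — not real magnitudes.
Wards are one per practice, with ranks drawn consistently with the drawn
quartiles; pharmacies are private to their practice (no sharing across
practices), which keeps extracted pharmacy counts exact but removes a real
feature of the data.

Consequently, a green test establishes that the pipeline recovers the
parameters of this stated world — not that real practices separate this
cleanly, and not any magnitude of the real prescribing differences.

All randomness flows from one master seed through `derive_seed(seed,
stream)` so stages are independently reproducible; identical config + seed
gives byte-identical pipeline outputs.

## 6. Numerical conventions and degenerate inputs

* Weighted median/SD follow exact multiset-expansion semantics (even-total
  windows average the two central values; SD is the population SD) and are
  property-tested against explicit expansion.
* Across-practice summaries use the sample SD; singleton clusters report
  `NA` rather than 0.
* Dispersion is undefined (`NA`) below two pharmacies and excluded, with
  counts, from cluster summaries.
* Joins are strict by default: unmatched location codes or unlabelled
  practices abort with the offending codes named. A permissive flag on the
  area join drops-and-warns instead, for exploratory use.
* RMSE refuses misaligned month vectors rather than truncating.
* `weighted_sd` requires total weight ≥ 2; `standardise` requires ≥ 2 rows
  and no constant column; `pca_project` requires ≥ 3 rows.

## 7. Known limitations

* Feature independence and per-practice pharmacies (above) make the
  synthetic world easier than the real one.
* The generator's items-per-patient separation inherits the implausibly
  tight published SDs; end-to-end label recovery is correspondingly easy.
* Only item counts are modelled — no costs, quantities, or drug-level
  (paragraph/chemical) structure.
* Deprivation is assigned by practice location, not by the deprivation of
  the population each practice serves.
* The pipeline assumes exactly two clusters downstream of k selection; if
  a different k is ever selected, labelling and two-cluster comparisons are
  skipped with a warning rather than forced.
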