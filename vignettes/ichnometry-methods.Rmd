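---
title: "Methods: biometric inference from footprint measurement tables"
author: "ichnometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biometric inference from footprint measurement tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ichnometry)
```

## Scope and data model

`ichnometry` works from *measurement tables*: one row per footprint, with
anatomical landmark distances in cm (digit-tip to heel-baseline lengths
Dt1–Dt5, medial/lateral ball, arch and heel lengths, ball/arch/heel
widths, maximum foot length and width) and two angles in degrees (toe
declination, arch angle). Units are fixed — cm and degrees throughout —
and no unit inference is attempted. Missing cells are first-class: they
are kept as `NA` from CSV to report, never zero-filled, and a sentinel
such as −1 is rejected as a negative measurement rather than silently
accepted. Decimal commas are accepted on input (the transcribed source
tables mix both conventions) and all output uses decimal points.
Left and right feet are treated as mirror-invariant scalar measurement
sets; no coordinate mirroring is applied, so both sides enter one
analysis together.

The packaged fixtures transcribe the published Bàsura cave tables: the
qualitative descriptor table with morphotype labels, the full measurement
and elaboration table (26 footprints), the published per-morphotype
summary rows, and the nine-variable table used for the multivariate
analysis (23 footprints). The summary rows of the source tables are
computed over subsets that the source never states explicitly; the
subsets encoded in the fixture (`summary_subset`) were reverse-engineered
arithmetically — they are the unique subsets whose mean ± sample SD
reproduces every printed summary cell — and are shipped as data, not
guessed at run time.

## Derived indices

The **foot index** is maximum width over maximum length. The source's
methods text defines it ×100, but its tables print the plain ratio
(0.46, 0.34, …); the package computes the ratio and leaves the percentage
form as an option, because the tables are the acceptance surface for
reproduction. The **arch angle** is the acute angle at the medial
metatarsal point between the medial border line and the line to the apex
of the arch concavity; it is computed from planar landmark coordinates by
a dot product and is invariant under rigid motion and uniform scaling.

## Log-shape PCA with iterative imputation

The nine lengths/widths are natural-log transformed before analysis.
Logs linearise allometric power relations, and isometric size change
becomes a common additive shift of all variables, so the first component
of a positively correlated measurement set reads as a size axis. The log
base is immaterial to the PCA (a uniform rescaling); natural log is used.

Missing cells (12 of 207 in the fixture) are completed by the standard
iterative scheme: initialise with column means, then iterate
(column-centre → rank-*k* SVD reconstruction → overwrite missing cells)
until the largest change of any imputed cell is below `tol` (default
1e−6) or `max_iter` (200) sweeps. Defaults: *k* = 3, covering the size
axis plus two shape axes. The procedure is deterministic, leaves observed
cells untouched, and is the identity on complete matrices. On exactly
rank-*k* data it recovers deleted cells exactly (tested against a rank-1
closed form).

The PCA itself is an eigen-analysis of the covariance matrix of the
column-centred log data (computed via SVD). Covariance, not correlation,
is used: all variables share log-cm units, and covariance preserves the
allometric reading of the loadings. Components are ordered by decreasing
variance, and each loading column is sign-fixed so its largest-magnitude
entry is positive — an arbitrary but deterministic convention. A constant
matrix (zero variance) is an error, not a degenerate result.

## Morphotype grouping and MNI

The source study groups footprints by physically overlapping outline
drawings that agree "within 2% of the main parameters". That rule cannot
be applied literally to the printed measurements — within-morphotype foot
length ranges reach 9–12%, far above 2% — so the package treats grouping
as a calibrated clustering problem and retains the per-group relative
size range as a diagnostic (`spread` in the assignment object).

Rows are compared by the mean absolute difference of log measurements
over variables present in both rows: a unit-free relative-difference
metric (a change of cm to mm shifts all logs by a constant that cancels
in differences). The hierarchy uses Ward linkage. Average linkage was
evaluated first and rejected: at any cut giving five groups on the
fixture it isolates one mid-sized footprint and merges the two largest
size classes, contradicting the unambiguous small/large memberships of
the published partition. The tree is cut at a *fraction* of its maximum
merge height (default 0.166) rather than an absolute height: Ward merge
heights grow with cluster size, so an absolute cut calibrated on one
table does not transfer to tables with more prints per producer, whereas
the relative cut does (it recovered the true producer count in 100/100
simulated replicates at 4, 5 and 8 prints per individual and ≥10%
foot-length separation, noise CV 0.03). The default was calibrated once
against the published five-morphotype partition, whose admissible window
on the fixture is 0.155–0.178.

Determinism: rows are sorted lexicographically by footprint id before
clustering, so the assignment is invariant to input row order; group
labels are renumbered by increasing mean size. The MNI is the group
count under the one-producer-per-morphotype assumption — a floor, not an
estimate, of the true party size.

## Biometric models

* **Stature**: FL / 0.1541. The ratio is carried as data
  (`stature_model()`), not re-fitted — the skeletal sample behind it is
  not printed. The tibia regressions (male 101.85 + 1.81·PCTL ± 3.73;
  female 77.86 + 2.36·PCTL ± 2.94) serve as an independent cross-check
  where kneeling traces give a tibial length.
* **Body mass**: model a (child exponential, 2.2897·e^(0.126·FL)),
  model b (adult linear, 4.71 + 1.82·FL), model c (child/adolescent
  linear, −71.142 + 5.259·FL, positive only above FL = 13.53 cm).
  Routing reproduces the source tables' pattern without per-row
  exceptions: adult-class groups (mean stature > 147 cm) get model b,
  plus model c when the group mean stature is ≤ 152 cm (model c was
  calibrated on a cohort averaging 147.44 cm, so it is kept near its
  calibration range and never applied to the tallest group); all smaller
  groups get model a. Mass uses the maximum foot length column (verified:
  one fixture footprint's printed mass requires max FL, not Dt1).
* **Age**: point age by linear interpolation between the growth anchors
  (1 yr, 13.07 cm) and (13 yr, 24.4 cm); below the first anchor the age
  is clamped to 1 and flagged extrapolated. Class bins were chosen to
  bracket the printed class assignments: age < 4.5 → `<3`, < 7 → `5-6`,
  < 12 → `8-11`, otherwise `>14 - adult`; adult-class morphology forces
  the adult label regardless of foot length (the growth curve is not
  informative above its anchors). The source prints `<3` for a group
  whose abstract calls the producer "about 3 years old"; the class string
  is emitted verbatim and the interpolated point age is reported
  alongside. Arch angles, when present, are compared against the
  juvenile development bands and reported as a consistency note only.
* **Sex**: a transparent rule table, conservative by default because the
  underlying method is explicitly speculative. `probable_male` requires
  the largest adult-class group, a stout profile (mean foot index ≥
  0.40), at least two footprints and an observed arch angle; an optional
  flag (`adult_gracile_female`) enables the probable-female reading of
  gracile adult groups; everything else is indeterminate. Every call
  carries its rationale and a low-confidence marker.

Group summaries are mean ± sample SD (n−1; verified: the printed SD of
the smallest group's stature requires the n−1 denominator), computed on
*unrounded* per-footprint values and rounded half-up to 2 decimals only
at the report boundary (verified: one printed group mass matches only
under this order of operations). Half-up rounding matches the source
tables' convention; base R's round-half-even does not.

## Synthetic trackways and parameter recovery

The generator inverts the biometric models so the estimation pipeline can
be tested against known truth. Individuals get an age (uniform in a
range, or fixed), an expected foot length from the growth reference
(linear between the anchors, continued to age 15 and constant beyond —
an adult plateau consistent with the fixture's adult foot lengths),
lognormal individual variation (CV configurable, default 5%), and a true
stature of FL / 0.1541. Footprints are the fixture's mean proportion
template (nine variables, rescaled so the foot length component is 1)
times the individual's foot length, with multiplicative lognormal
per-cell noise — measurements are positive lengths, and substrate
plasticity distorts them proportionally. The default noise CV of 0.03
(≈0.6 cm at adult foot lengths) sits at the landmark-reliability bound
reported for the original material; it is a package choice, not a
published value. Missingness is MCAR by default, with an optional
digit-block pattern (the three digit lengths lost together) mirroring the
fixture's blank digit blocks.

With zero noise the pipeline inverts the generator exactly: grouping
recovers the producer count, and stature/mass estimates equal the truth
to machine precision. `recovery_experiment()` runs replicated scenarios
(replicate *r* reseeds the simulator with `seed + r`) and reports MNI
accuracy, stature bias/RMSE, per-model mass RMSE and the age-class
confusion table. Problem sizes used in the shipped tests — 5 producers,
4–5 prints each, 2–100 replicates — keep every experiment desk-scale.

What the generator does *not* emulate: systematic substrate deformation
(expulsion rims, slippage), within-individual left/right asymmetry,
correlated shape deviation from the common template, and non-random
missingness tied to preservation quality. Passing recovery tests
therefore demonstrate correctness of the inference machinery under the
stated noise model, not robustness to every taphonomic regime.

## Numerical and edge-case policy

Non-positive measurements are read errors; validation issues
(width exceeding length, arch angle outside (0°, 90°)) are returned as
issue lists, never raised, and validation never mutates a record.
Identical duplicated rows cluster to one group; a single footprint is its
own group; an empty table is an error. Imputation requires every column
to hold at least two observed values and `k < min(rows, cols)`.
Clustering ties are broken deterministically by the lexicographic row
order. Reports print `± n/a` for single-member groups.

## Known limitations

* The grouping cut is calibrated to one published partition; assemblages
  with very different print-per-producer balance or heavy missingness may
  need `cut` adjusted (the admissible fixture window 0.155–0.178 gives a
  sense of the sensitivity).
* The stature ratio and mass models are population-level calibrations on
  modern or skeletal reference samples; systematic offsets for other
  populations propagate directly into the estimates.
* Age classes above the 13-year anchor rest on morphology, not the growth
  curve; the `>14 - adult` bin is open-ended.
* Sex inference is a labelled speculation, deliberately so.
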