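---
title: "Station partitioning, recurrence mapping and the prediction pipeline: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Station partitioning, recurrence mapping and the prediction pipeline: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

In radiotherapy for small cell lung cancer, the clinical target volume (CTV)
is drawn to cover gross disease — the primary tumor (GTV) and visibly
involved lymph nodes (GTVnd) — plus the mediastinal and hilar lymph-node
stations suspected of microscopic spread. Local recurrences cluster in
specific stations, and how completely a delineation covered the stations it
touched is a candidate predictor of failure. `ctvrecur` quantifies this:
it partitions a patient's CTV against the sixteen IASLC station labels
(1R, 1L, 2R, 2L, 3A, 3P, 4R, 4L, 5, 6, 7, 8, 10R, 10L, 11R, 11L), derives a
110-parameter overlap feature vector, maps recurrence regions to
station-level events, and fits a screened bagged-tree model predicting
relapse, alongside Kaplan–Meier / Cox local-control analyses.

All statistics operate on co-registered binary masks on one shared voxel
grid. A voxel belongs to a structure iff its mask value is 1; volumes are
voxel counts times the voxel volume, with no partial-volume weighting —
every ratio below is a ratio of voxel counts, so the voxel volume cancels.
Masks must be pre-resampled to the shared grid; the package never resamples,
which removes interpolation ambiguity from the ratio definitions. Station
masks must be pairwise disjoint: the ratio families silently double-count
under overlap, so overlap is a hard validation error, never auto-repaired.

# The ideal CTV and the six ratio families

A station is *violated* (touched) when the CTV overlaps it in at least
`min_overlap_voxels` voxels (default 1 — any overlap, the strict reading of
"> 0"). The **ideal CTV** is the union of the *full* masks of every violated
station: touching a single voxel of station 4L pulls all of 4L into the
ideal CTV. It represents the target that a delineation intending to treat
every violated station completely would have used, and it is the
normalizing volume of the `RI*` families.

With `G` the gross-disease mask and `|.|` voxel counts, for each station
`i` in 1..16:

* `RctvLNi = |CTV ∩ LNi| / |LNi|` — how completely the CTV covers the station;
* `RIctvLNi = |CTV ∩ LNi| / |ideaCTV|` — the station's share of the ideal target;
* `RgtvLNi = |G ∩ LNi| / |LNi|`, `RIgtvLNi = |G ∩ LNi| / |ideaCTV|` — the same
  pair for gross disease;
* `RcmgLNi = |(CTV − G) ∩ LNi| / |LNi|`, `RIcmgLNi = |(CTV − G) ∩ LNi| / |ideaCTV|`
  — the prophylactic (CTV-minus-gross) component.

Useful exact identities follow from the definitions and are enforced as
tests: `RcmgLNi = RctvLNi − RgtvLNi` whenever `G ⊆ CTV`, and because
stations are disjoint, `Σᵢ RIctvLNi ≤ 1` with equality iff the CTV covers
the whole ideal CTV.

Two choices the definitions leave open:

* **What is `G`?** The ratio formulas say "GTV", but nodal gross disease is
  tracked separately and the stations are nodal territory: with primary-only
  gross disease most `RgtvLNi` would be identically zero. Default is
  `G = GTV ∪ GTVnd` (all gross disease), with
  `gross_disease = "primary_only"` available on every extraction function.
* **Empty ideal CTV.** A CTV touching no station is a legal degenerate input
  (it happens in small synthetic cohorts); the `RI*` ratios are then defined
  as 0 with a warning, keeping feature matrices numeric rather than
  introducing NaNs.

The full 110-vector (`extract_features()`) appends fourteen scalars to the
96 ratios: CTV and GTVnd volumes in mm³, the in-plane voxel spacing in mm,
the counts of stations involved by CTV and by GTVnd, a lung-quadrant code,
seven binary flags for CTV contact with stations 4L, 4R, 5, 6, 7, 11L, 11R,
and the pre-treatment tumor size from the clinical record. The quadrant
code (1 right-upper, 2 right-lower, 3 left-upper, 4 left-lower, by GTV
centroid) is a convention this package fixes — the source schema lists codes
1–4 without defining them — and the synthetic generator uses the same
convention, so generation and extraction agree.

# Recurrence mapping

`classify_recurrence()` produces one event per (patient, station) with
`|recurrence ∩ LN_s| > 0`; a connected recurrence straddling k stations
yields k events, which is why cohort event totals exceed patient counts. An
event is *GTV-affected* if the recurrence touches gross disease within the
station, else a *CTV−GTV* event; gross-disease contact takes precedence, so
the split is exclusive and sums to the station total. The tally's
`actual_over_idea` column is interpreted as `|CTV ∩ LN_s| / |LN_s|` for the
event's station — the fraction of the ideal station volume the delineation
actually covered. This matches the column's 0–1 range and its framing as a
measure of under-coverage; the interpretation is isolated in one place
(`classify_recurrence()`) so an alternative reading is a one-line change.
A bundled reference table (`recurrence_tally_reference()`) carries the
published per-station tally of a 180-patient cohort (170 events, 105
GTV-affected);
`events_from_counts()` reconstructs a flat event list from such printed
counts so the aggregation arithmetic can be re-run exactly.

# The prediction pipeline

`fit_recurrence_pipeline()` runs, on training rows only:

1. **Standardization** — centre and scale by the *population* standard
   deviation (denominator n); constant columns map to zeros and are
   flagged. The stored transform is applied unchanged to validation rows.
2. **Correlation filter** — pairs with `|Pearson r| ≥ 0.95` are redundant;
   the member with the weaker absolute point-biserial correlation to the
   label is dropped, ties keeping the earlier schema column. Deterministic
   given column order.
3. **RFE with stratified 5-fold CV** — repeatedly fit the ensemble per
   fold, record mean held-out AUC at the current subset size, average
   impurity importances over folds, drop the lowest-ranked `step` (default
   1) feature. Selected subset: highest mean CV AUC, ties to the smaller
   subset. The internal ranking ensemble uses 50 trees of depth ≤ 7 —
   importance estimates are averaged over five folds per step, so modest
   per-fit resolution suffices and keeps the 110-feature path tractable.
4. **Bagged trees with grid search** — probability forests over
   depth ∈ {3, 5, 7, unbounded} × B ∈ {100, 200, 500}, scored by stratified
   5-fold CV AUC. Scores are tree-averaged probabilities (the
   `RF(x) = (1/B) Σ Tᵢ(x)` form); class labels are the majority vote of the
   trees, computed from per-tree predictions — both conventions are exposed
   because the source method describes both, averaging for ROC/AUC and
   voting for labels.
5. **Evaluation** — accuracy, precision, recall and F1 at the 0.5
   threshold; AUC by the Mann–Whitney rank statistic (midranks for ties,
   equal to trapezoidal ROC integration and invariant under monotone score
   transforms); the ROC over all unique thresholds.

The split (default 80/20, stratified) happens before anything is fitted,
and a leakage test in the suite verifies that permuting validation labels
changes no fitted quantity. The correlation threshold, RFE step, CV fold
count, grid values and the 0.5 threshold are configuration keys with the
stated defaults — none of them is tuned per dataset inside the package.
The screening's selected subset size is data-driven; no target
dimensionality is hard-coded.

# Survival analyses

Local control is analysed with standard machinery from the `survival`
package behind thin, contract-checked wrappers: the Kaplan–Meier
product-limit estimator (events before censorings at tied times; the
"3-year local-control rate" is the curve at 36 months), the two-group
log-rank test with hypergeometric variance, and univariate Cox regression
for a binary covariate (Newton–Raphson, Breslow ties by default with Efron
available, tolerance 1e-8, 50 iterations; monotone-likelihood divergence is
converted into an informative error). `contingency_2x2()` gives the odds
ratio with a Woolf interval and a continuity-corrected chi-square p-value,
switching to Fisher's exact test when an expected cell is below 5.
Multivariate Cox on the full covariate set is deliberately out of scope:
it is not estimable without per-patient clinical data, which are not
available.

# The synthetic phantom cohort

No clinical images ship with the package, so every downstream stage is
exercised on synthetic structure sets with known ground truth.

**Atlas.** Sixteen ellipsoidal stations in a stylized mediastinal layout
(superior 1R/1L above 2R/2L; 3A anterior, 3P posterior; subcarinal 7
central; 8 inferior; hilar/interlobar 10R/10L/11R/11L lateral-inferior),
defined in fractions of the grid's physical extent so the same anatomy
scales to any grid. Default grid: 96³ voxels at 1.5 mm isotropic (a 144 mm
cube) — chosen for desk-scale runtime; a clinical-like 512×512 grid with
5 mm slices is available through `voxel_grid()`. Because a voxel belongs to
an ellipsoid iff its centre does, disjoint continuous ellipsoids always
rasterize to disjoint masks; overlap requested by a custom spec is an error
naming the colliding pair.

**Patient geometry.** The GTV is an ellipsoid at a sampled lung-quadrant
location with diameter ~N(4.8 cm, 1.6 cm) truncated to [1.5, 9]; nodal
involvement is Bernoulli per station (defaults hilar-dominant: 10R 0.45,
10L/4R 0.35, 7 0.30, tapering to 0.03 for 2L/3P); GTVnd is a sub-ellipsoid
inside each involved station; the CTV is the morphological dilation of
GTV ∪ GTVnd by an 8 mm margin, unioned with the involved stations' full
masks and clipped to the grid. Dilation partially spills into neighbouring
stations, which is what makes the coverage ratios take values strictly
between 0 and 1 rather than degenerating to {0, 1}. Dilation is computed
by FFT convolution with the Euclidean ball's indicator on a zero-padded
grid — exact (tested voxel-for-voxel against the union-of-shifts
definition) and about 25× faster than explicit shifting at 96³.

**Planted outcome model.** The relapse label is Bernoulli from a logistic
model on the cohort-standardized true features; coefficients are therefore
log-odds per standard deviation, comparable across features of different
scales. Defaults: intercept 0.1 and five informative features
(`RgtvLN13` 1.2, `RgtvLN14` 1.0, `RctvLN7` 1.0, `RctvLN11` 1.0, `gtv_size`
1.0) — gross-disease coverage of the hilar stations, CTV coverage of 4R and
7, and tumor size — giving a relapse fraction near 52%, the prevalence the
study conditions call for. Time-to-recurrence is exponential with hazard
0.04/month times a hazard ratio of 1.635 for tumors ≥ 5 cm; censoring is an
independent exponential (rate 1/60 per month), observed follow-up the
minimum of the two. Relapsing patients receive one connected recurrence
ellipsoid in a station sampled with weights mirroring the published
per-station prevalence (hilar-dominant), seeded at the patient's own nodal
disease with probability 105/170 (the published GTV-affected share);
multi-station events arise when the ellipsoid straddles a boundary. All of
these defaults are generator choices fixed once to emulate the study
conditions, not estimates from data.

**Two generator layers.** `generate_cohort()` builds full voxel phantoms
and is used wherever geometry matters (feature extraction, recurrence
mapping, I/O, end-to-end determinism). `simulate_feature_cohort()` draws
110-column feature vectors directly from the involvement model — involved
stations fully covered, partial spill-over on others, shared ideal-CTV
denominator, `Rcmg = Rctv − Rgtv` exact — and plants the same logistic
labels. It exists because the screening/model experiments need hundreds of
patients across many seeded replicates, where rasterizing voxel phantoms
adds hours without adding information about the statistical pipeline. What
passing those experiments shows is that the pipeline recovers planted
signal of the stated strength at the stated sample sizes — not that real
SCLC cohorts carry such signal, nor that real anatomy resembles the
phantoms. Deformable anatomy, CT intensities and true IASLC boundary
definitions are explicitly not modelled.

**Randomness.** One master seed; every stage and every patient draws from a
labelled substream (`substream_seed()`), so cohorts are reproducible
independent of evaluation order, and `run_all()` is byte-identical across
reruns with the same configuration.

# Numerical and degenerate-input choices

* Ratios are ratios of integer voxel counts: exact in double precision; the
  brute-force recount equivalence in the test suite is asserted at 1e-14.
* Empty masks: Dice of two empty masks is 1 (two empty delineations agree);
  Hausdorff of an empty mask is an error (undefined).
* Hausdorff uses boundary voxel centres (6-neighbourhood boundary, grid-edge
  voxels count as boundary), scaled anisotropically by spacing, computed by
  chunked exact all-pairs max–min.
* KM/log-rank/Cox inherit `survival`'s tie conventions (Breslow default);
  the log-rank p-value is checked against a 2000-permutation null in the
  suite, and the Cox estimate against direct maximization of the Breslow
  partial likelihood.
* Constant feature columns standardize to zero and are excluded from
  correlation-filter comparisons (their correlations are undefined).

# Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run at sizes chosen for a
single-CPU desk machine: geometry tests on 30³–48³ grids (one schema check
on the default 96³ grid), oracle equivalence on 20 phantoms at 48³,
screening recovery on planted logistic designs (5 informative columns with
per-SD coefficients ≥ 1 among 105 independent noise columns — named-feature
recovery is only well-posed against a non-redundant background, since the
schema's ratio families contain near-collinear proxies through which RFE
can retain the same information under another name), AUC experiments on
feature-level cohorts of 400–500 over 10–20 seeded replicates, survival
recovery at n = 1000, and
end-to-end determinism at n = 24 on a 48³ grid (determinism is
size-independent). The default configuration (`run_config()`: n = 180 at
96³) runs the identical code path in a few minutes.

# Known limitations

* The phantom anatomy is stylized; absolute volumes and station adjacencies
  are plausible but not anatomical truth, so learned models transfer no
  clinical meaning.
* The recurrence-proportion column's definition is an interpretation (see
  above); published per-event values cannot be reconstructed from printed
  means and ranges.
* Only univariate survival contrasts are supported; competing risks and
  time-varying covariates are out of scope.
* DICOM/DICOM-RT parsing is out of scope: masks arrive as NIfTI volumes
  already resampled to a common grid.
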