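# ctvrecur

Station-level partitioning of radiotherapy clinical target volumes (CTV)
and recurrence prediction for small cell lung cancer.

When a CTV for thoracic radiotherapy is delineated, it touches some of the
sixteen mediastinal/hilar lymph-node stations of the IASLC map (1R, 1L, 2R,
2L, 3A, 3P, 4R, 4L, 5, 6, 7, 8, 10R, 10L, 11R, 11L). How completely the
delineation covered the stations it touched — and which stations the gross
disease involved — carries information about where and whether the tumor
will recur. `ctvrecur` is for researchers analysing this relationship on
co-registered binary masks: it computes station-overlap feature vectors,
maps recurrence regions to station-level events, fits a feature-screened
bagged-tree recurrence classifier, and runs local-control survival
contrasts. Because clinical mask data rarely travel, the package also ships
a synthetic mediastinal phantom generator with planted ground truth, so the
entire pipeline is testable end to end.

## The core constructs

All quantities are ratios of voxel counts of masks on one shared grid.
A station `LNi` is *violated* when the CTV overlaps it at all, and the
**ideal CTV** is the union of the *full* masks of every violated station:

```
ideaCTV = ∪ { LNi : |CTV ∩ LNi| > 0 }
```

Six ratio families per station (with `G` the gross disease, GTV ∪ GTVnd by
default) form the backbone of the 110-parameter feature vector:

```
RctvLNi  = |CTV ∩ LNi| / |LNi|        RIctvLNi = |CTV ∩ LNi| / |ideaCTV|
RgtvLNi  = |G ∩ LNi|   / |LNi|        RIgtvLNi = |G ∩ LNi|   / |ideaCTV|
RcmgLNi  = |(CTV−G) ∩ LNi| / |LNi|    RIcmgLNi = |(CTV−G) ∩ LNi| / |ideaCTV|
```

plus fourteen scalars (volumes, image resolution, involvement counts,
station contact flags, tumor size). The prediction model standardizes the
features, removes correlated redundancy (|r| ≥ 0.95), screens by recursive
feature elimination under stratified 5-fold cross-validated AUC, and fits
bagged decision trees (probability averaging `RF(x) = (1/B) Σ Tᵢ(x)` for
scores, majority voting for labels) with tree depth and ensemble size
grid-searched. Survival analyses cover Kaplan–Meier curves, fixed-horizon
local-control rates, the log-rank test, univariate Cox hazard ratios and
2×2 contingency statistics; Dice and Hausdorff metrics evaluate mask
agreement.

## Worked example

```r
library(ctvrecur)

# a synthetic patient on a 48^3 grid (1.5 mm voxels)
atlas <- generate_atlas(atlas_spec(voxel_grid(c(48L, 48L, 48L), rep(1.5, 3))))
p <- generate_patient(atlas, effect_spec(), seed = 42)
fv <- extract_features(p$ss, p$record)
round(fv[c("RctvLN13", "RIctvLN13", "RgtvLN13", "n_ln_ctv", "ctv_volume", "gtv_size")], 4)
#>   RctvLN13  RIctvLN13   RgtvLN13   n_ln_ctv ctv_volume   gtv_size
#>     1.0000     0.3288     0.2778     4.0000 21411.0000     5.3810
```

This patient's CTV fully covers hilar station 10R (`RctvLN13 = 1`), which
makes up 33% of the ideal target; nodal disease occupies 28% of the
station; the CTV touches 4 stations in total and measures 21 411 mm³.

Re-running the published aggregate arithmetic from the bundled reference
tally:

```r
tal <- tally_by_station(events_from_counts(recurrence_tally_reference()))
tal$total                                        # 170 station-level events
top_station_share(tal, c("10R", "10L", "4R", "7"))  # 0.6765  (115/170)
```

And the full screened prediction pipeline on a planted feature cohort:

```r
sim <- simulate_feature_cohort(500, effect_spec(), seed = 1)
rep <- fit_recurrence_pipeline(sim$features, sim$features$relapse, seed = 1)
rep
#> <recurrence_model_report: 110 -> 50 features, depth unbounded, 200 trees>
#> training:   accuracy       auc precision    recall        f1
#>     0.990     1.000     0.995     0.985     0.990
#> validation: accuracy       auc precision    recall        f1
#>     0.730     0.825     0.729     0.714     0.722
```

The validation AUC of 0.83 reflects the planted five-feature logistic
signal; the train/validation gap is the expected forest optimism. An
end-to-end run — simulate, extract, map recurrences, train, survival —
lives behind one seeded call:

```r
res <- run_all(run_config(master_seed = 17, n = 40,
                          grid_shape = c(48L, 48L, 48L),
                          grid_spacing = rep(1.5, 3)),
               out_dir = "run17")
render_report("run17")   # markdown: station tally, metric grid, KM contrast
```

A thin command-line wrapper is included at `inst/cli/ctvrecur.R`
(`run-all`, `simulate`, `report`).

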