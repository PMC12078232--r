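test_that("atlas generation is deterministic, disjoint and non-empty", {
  a1 <- generate_atlas(atlas_spec(small_grid(48)))
  a2 <- generate_atlas(atlas_spec(small_grid(48)))
  expect_identical(a1$masks, a2$masks)
  occ <- Reduce(`+`, lapply(a1$masks, function(m) m + 0L))
  expect_lte(max(occ), 1L)
  expect_true(all(vapply(a1$masks, any, logical(1))))
  # stylized anatomy: superior stations above the paratracheal row,
  # subcarinal station 7 central, hilar stations lateral
  cz <- function(lab) {
    idx <- which(a1$masks[[lab]], arr.ind = TRUE)
    mean(idx[, 3])
  }
  expect_gt(cz("1R"), cz("2R"))
  expect_gt(cz("2R"), cz("7"))
})

test_that("oversized station ellipsoids raise an overlap error naming a pair", {
  spec <- atlas_spec(small_grid(32, 1), radius_scale = 3)
  expect_error(generate_atlas(spec), "overlap", class = "ctv_atlas_error")
})

test_that("generated patients satisfy structure-set invariants by construction", {
  atlas <- small_atlas(48)
  for (seed in c(3, 14, 27)) {
    p <- generate_patient(atlas, effect_spec(), seed = seed)
    expect_equal(nrow(validate_structure_set(p$ss)), 0)
    # nodal disease appears exactly in the involved stations
    for (i in 1:16) {
      hit <- sum(p$ss$gtvnd & atlas$masks[[i]]) > 0
      expect_identical(unname(hit), unname(p$involved[i]))
    }
  }
})

test_that("zero margin and no involved stations give CTV equal to GTV", {
  atlas <- small_atlas(48)
  eff <- effect_spec(involved_station_probs = setNames(rep(0, 16), station_labels()))
  p <- generate_patient(atlas, eff, seed = 8, margin_mm = 0)
  expect_identical(p$ss$ctv, p$ss$gtv)
  expect_false(any(p$ss$gtvnd))
})

test_that("GTV volume tracks the analytic ellipsoid volume at fine spacing", {
  # isolate the primary: no stations involved, no margin, fine 1 mm grid
  g <- voxel_grid(c(144L, 144L, 144L), c(1, 1, 1))
  atlas <- generate_atlas(atlas_spec(g))
  eff <- effect_spec(involved_station_probs = setNames(rep(0, 16), station_labels()))
  p <- generate_patient(atlas, eff, seed = 12, margin_mm = 0)
  vol <- volume_mm3(p$ss$gtv, g)
  analytic <- 4 / 3 * pi * prod(p$gtv_geometry$semi_axes)
  expect_lt(abs(vol - analytic) / analytic, 0.05)
})

test_that("cohorts are reproducible and internally consistent", {
  atlas <- small_atlas(32)
  c1 <- generate_cohort(6, atlas, effect_spec(), seed = 99)
  c2 <- generate_cohort(6, atlas, effect_spec(), seed = 99)
  expect_identical(c1$features, c2$features)
  expect_identical(c1$outcomes, c2$outcomes)
  expect_identical(lapply(c1$patients, function(p) p$ss$ctv),
                   lapply(c2$patients, function(p) p$ss$ctv))
  # every generated structure set passes validation
  for (p in c1$patients) expect_equal(nrow(validate_structure_set(p$ss)), 0)
  # relapse=1 patients carry a recurrence mask; relapse=0 patients do not
  for (i in seq_along(c1$patients)) {
    if (c1$outcomes$relapse[i] == 1) {
      expect_true(any(c1$patients[[i]]$ss$recurrence))
    } else {
      expect_null(c1$patients[[i]]$ss$recurrence)
    }
  }
  expect_error(generate_cohort(1, atlas), class = "ctv_cohort_error")
})

test_that("with no censoring the event indicator matches the planted label", {
  atlas <- small_atlas(32)
  eff <- effect_spec(censoring_rate = 0)
  co <- generate_cohort(10, atlas, eff, seed = 4)
  expect_identical(co$outcomes$event, as.numeric(co$outcomes$relapse))
})

test_that("a null planted model yields a relapse rate near one half", {
  eff <- effect_spec(logit_intercept = 0, logit_coefficients = numeric(0))
  sim <- simulate_feature_cohort(2000, eff, seed = 31)
  rate <- mean(sim$features$relapse)
  # 3 standard errors of a fair coin at n = 2000
  expect_lt(abs(rate - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("a planted +2 coefficient raises relapse among involved patients", {
  eff <- effect_spec(logit_intercept = 0,
                     logit_coefficients = c(RctvLN13 = 2))
  sim <- simulate_feature_cohort(1000, eff, seed = 13)
  involved <- sim$features$RctvLN13 == 1
  expect_gt(mean(sim$features$relapse[involved]),
            mean(sim$features$relapse[!involved]))
  # empirical rates bracket the logistic closed form given the latent lp
  expect_lt(abs(mean(sim$features$relapse) - mean(sim$truth$p_relapse)),
            3 * sqrt(mean(sim$truth$p_relapse * (1 - sim$truth$p_relapse)) / 1000))
})

test_that("uncensored covariate-free event times follow the exponential law", {
  atlas <- small_atlas(24, 2)
  eff <- effect_spec(logit_intercept = 20, logit_coefficients = numeric(0),
                     censoring_rate = 0, baseline_hazard = 0.05,
                     hazard_ratio_per_unit = numeric(0))
  # a CTV may legitimately touch no station on this coarse grid; the
  # resulting degenerate-ratio warning is not under test here
  co <- suppressWarnings(generate_cohort(80, atlas, eff, seed = 55))
  expect_true(all(co$outcomes$relapse == 1))
  ks <- suppressWarnings(
    stats::ks.test(co$outcomes$time, "pexp", rate = 0.05))
  expect_gt(ks$p.value, 0.01)
  km <- kaplan_meier(co$outcomes$time, co$outcomes$event)
  expect_lt(abs(lc_rate_at(km, 10) - exp(-0.5)), 0.2)
})
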