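test_that("recurrence events are classified per station with GTV precedence", {
  ln <- box_station_masks()
  grid <- box_station_grid()
  # recurrence wholly inside LN13 (10R) and touching nodal disease there
  gtvnd <- array(FALSE, grid$shape)
  v13 <- which(ln[[13]], arr.ind = TRUE)
  gtvnd[v13[1, 1], v13[1, 2], v13[1, 3]] <- TRUE
  rec <- array(FALSE, grid$shape)
  rec[v13[1:8, ]] <- TRUE
  ctv <- ln[[13]] # CTV covers the station fully
  ss <- box_structure_set(ctv, gtvnd = gtvnd, recurrence = rec)
  ev <- classify_recurrence(ss, "pA")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$station_label, "10R")
  expect_equal(ev$gtv_affected, 1L)
  expect_equal(ev$actual_over_idea, 1)

  # recurrence straddling LN11 (7) and LN7 (4R), no gross disease contact
  rec2 <- array(FALSE, grid$shape)
  v11 <- which(ln[[11]], arr.ind = TRUE)
  v7 <- which(ln[[7]], arr.ind = TRUE)
  rec2[v11[1:4, ]] <- TRUE
  rec2[v7[1:4, ]] <- TRUE
  ss2 <- box_structure_set(ctv, recurrence = rec2)
  ev2 <- classify_recurrence(ss2, "pB")
  expect_setequal(ev2$station_label, c("4R", "7"))
  expect_true(all(ev2$gtv_affected == 0L))

  # recurrence outside all stations: zero events, voxels flagged out-of-atlas
  rec3 <- box_mask(grid, c(1, 1, 25), c(3, 3, 27))
  ss3 <- box_structure_set(ctv, recurrence = rec3)
  ev3 <- classify_recurrence(ss3, "pC")
  expect_equal(nrow(ev3), 0)
  expect_equal(attr(ev3, "out_of_atlas_voxels"), 27)

  ss_none <- box_structure_set(ctv)
  expect_error(classify_recurrence(ss_none), "no recurrence",
               class = "ctv_no_recurrence")
})

test_that("per-station tallies conserve counts and are permutation invariant", {
  ref <- recurrence_tally_reference()
  ev <- events_from_counts(ref)
  tal <- tally_by_station(ev)
  expect_equal(tal$total, 170)
  expect_equal(tal$by_station$n_gtv_affected + tal$by_station$n_ctv_minus_gtv,
               tal$by_station$n_events)
  expect_equal(sum(tal$by_station$n_events), tal$total)
  # reproduces the reference counts row for row
  expect_equal(tal$by_station$n_events, ref$n_events)
  expect_equal(tal$by_station$n_gtv_affected, ref$n_gtv_affected)
  expect_equal(tal$by_station$mean_actual_over_idea, ref$mean_actual_over_idea)
  # zero-event stations show NA proportions
  expect_true(all(is.na(
    tal$by_station$mean_actual_over_idea[tal$by_station$n_events == 0])))
  # permutation invariance
  tal2 <- tally_by_station(ev[sample(nrow(ev)), ])
  expect_equal(tal2$by_station, tal$by_station)
  # empty event list -> all-zero tallies
  tal0 <- tally_by_station(ev[0, ])
  expect_equal(tal0$total, 0)
  expect_true(all(tal0$by_station$n_events == 0))
})

test_that("top_station_share normalizes event counts", {
  tal <- tally_by_station(events_from_counts(recurrence_tally_reference()))
  expect_equal(top_station_share(tal, c("10R", "10L", "4R", "7")), 115 / 170)
  expect_equal(top_station_share(tal, station_labels()), 1)
  expect_equal(top_station_share(tal, c("2L", "3P")), 0)
  expect_error(top_station_share(tally_by_station(events_from_counts(
    recurrence_tally_reference()[0, ])), "7"), class = "ctv_tally_error")
})

test_that("initial-involvement recurrence rates equal a direct recount", {
  sim <- simulate_feature_cohort(300, effect_spec(), seed = 19)
  rates <- initial_region_recurrence_rates(sim$features)
  for (i in c(3, 7, 13)) {
    inv <- sim$features[[paste0("RgtvLN", i)]] > 0
    n_inv <- sum(inv)
    expected <- if (n_inv > 0) sum(sim$features$relapse[inv]) / n_inv else NA_real_
    expect_equal(rates$rate[i], expected)
  }
  # a station nobody involves reports NA
  none <- sim$features
  none$RgtvLN6 <- 0
  expect_true(is.na(initial_region_recurrence_rates(none)$rate[6]))
  # constructed certainty: every station-13-involved patient relapses
  forced <- sim$features
  forced$relapse[forced$RgtvLN13 > 0] <- 1L
  expect_equal(initial_region_recurrence_rates(forced)$rate[13], 1)
})

test_that("cohort recurrence mapping conserves per-station splits", {
  atlas <- small_atlas(32)
  co <- generate_cohort(30, atlas, effect_spec(), seed = 3)
  ev <- classify_cohort_recurrences(co)
  tal <- tally_by_station(ev)
  expect_equal(tal$by_station$n_gtv_affected + tal$by_station$n_ctv_minus_gtv,
               tal$by_station$n_events)
  expect_equal(sum(tal$by_station$n_events), tal$total)
  expect_gte(tal$total, sum(co$outcomes$relapse == 1 &
                              !is.na(co$truth$per_patient$recurrence_station)))
})
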