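test_that("idea CTV is the union of whole touched stations", {
  ln <- box_station_masks()
  grid <- box_station_grid()
  # CTV = one voxel inside LN7 plus one voxel inside LN13
  v7 <- which(ln[[7]], arr.ind = TRUE)[1, ]
  v13 <- which(ln[[13]], arr.ind = TRUE)[1, ]
  ctv <- array(FALSE, grid$shape)
  ctv[v7[1], v7[2], v7[3]] <- TRUE
  ctv[v13[1], v13[2], v13[3]] <- TRUE
  ss <- box_structure_set(ctv)
  expect_identical(idea_ctv(ss), ln[[7]] | ln[[13]])

  # one-voxel contact pulls in the WHOLE station, not just the voxel
  ctv1 <- array(FALSE, grid$shape)
  v8 <- which(ln[[8]], arr.ind = TRUE)[1, ]
  ctv1[v8[1], v8[2], v8[3]] <- TRUE
  expect_identical(idea_ctv(box_structure_set(ctv1)), ln[[8]])

  # CTV away from every station -> empty idea CTV
  ctv0 <- box_mask(grid, c(1, 1, 25), c(5, 5, 28))
  expect_false(any(idea_ctv(box_structure_set(ctv0))))
})

test_that("idea CTV is a fixed point under CTV expansion to itself", {
  atlas <- small_atlas(48)
  p <- generate_patient(atlas, effect_spec(), seed = 21)
  idea1 <- idea_ctv(p$ss)
  ss2 <- p$ss
  ss2$ctv <- ss2$ctv | idea1
  expect_identical(idea_ctv(ss2), idea1)
})

test_that("ratio families reproduce hand-computed coverage fractions", {
  ln <- box_station_masks()
  grid <- box_station_grid()
  # CTV covers exactly half of LN7 (2 of 4 x-columns = 32 of 64 voxels)
  idx <- which(ln[[7]], arr.ind = TRUE)
  xs <- sort(unique(idx[, 1]))
  ctv <- ln[[7]]
  ctv[xs[3]:xs[4], , ] <- FALSE
  ss <- box_structure_set(ctv)
  r <- ratio_families(ss)
  expect_equal(unname(r["RctvLN7"]), 0.5)
  expect_equal(unname(r["RgtvLN7"]), 0)
  expect_equal(unname(r["RcmgLN7"]), 0.5)
  expect_equal(unname(r["RIctvLN7"]), 0.5) # idea = LN7 (64 vox), overlap 32

  # CTV identical to LN13 and touching nothing else
  ss13 <- box_structure_set(ln[[13]])
  r13 <- ratio_families(ss13)
  expect_equal(unname(r13["RIctvLN13"]), 1)
  expect_equal(unname(r13[paste0("RIctvLN", c(1:12, 14:16))]),
               rep(0, 15))

  # CTV touching no station: RI* are zero with a warning
  ctv0 <- box_mask(grid, c(1, 1, 25), c(4, 4, 28))
  expect_warning(r0 <- ratio_families(box_structure_set(ctv0)),
                 "touches no")
  expect_true(all(r0[17:32] == 0))
})

test_that("ratio families agree with an index-set recount on random phantoms", {
  atlas <- small_atlas(48)
  for (seed in c(2, 9, 33)) {
    p <- generate_patient(atlas, effect_spec(), seed = seed)
    expect_equal(ratio_families(p$ss), oracle_ratios(p$ss), tolerance = 1e-14)
    expect_equal(ratio_families(p$ss, "primary_only"),
                 oracle_ratios(p$ss, "primary_only"), tolerance = 1e-14)
  }
})

test_that("gross-disease ratios respect ordering and decomposition invariants", {
  atlas <- small_atlas(48)
  p <- generate_patient(atlas, effect_spec(), seed = 17)
  r <- ratio_families(p$ss)
  rctv <- r[1:16]; rgtv <- r[33:48]; rcmg <- r[65:80]
  expect_true(all(rgtv <= rctv + 1e-15))
  expect_equal(unname(rcmg), unname(rctv - rgtv))
  # disjoint stations: RIctv sums to the covered fraction of ideaCTV, <= 1
  expect_lte(sum(r[17:32]), 1 + 1e-12)
})

test_that("scalar features count involvement and carry record covariates", {
  ln <- box_station_masks()
  grid <- box_station_grid()
  # CTV touching stations 7 (4R), 11 (7) and 13 (10R) only
  ctv <- ln[[7]] | ln[[11]] | ln[[13]]
  ss <- box_structure_set(ctv)
  sc <- scalar_features(ss, dummy_record(lung_area_code = 2L,
                                         tumor_diameter_cm = 5.5))
  expect_equal(unname(sc["n_ln_ctv"]), 3)
  expect_equal(unname(sc["overlap_4R"]), 1)
  expect_equal(unname(sc["overlap_7"]), 1)
  expect_equal(unname(sc["overlap_4L"]), 0)
  expect_equal(unname(sc["n_ln_gtvnd"]), 0)
  expect_equal(unname(sc["gtvnd_volume"]), 0)
  expect_equal(unname(sc["lung_area_code"]), 2)
  expect_equal(unname(sc["gtv_size"]), 5.5)
})

test_that("in-plane spacing is reported as the image resolution", {
  g <- voxel_grid(c(16, 16, 8), c(1.1543, 1.1543, 5))
  ln <- lapply(1:16, function(i) {
    m <- array(FALSE, g$shape); m[i, 1, 1] <- TRUE; m
  })
  ctv <- Reduce(`|`, ln)
  empty <- array(FALSE, g$shape)
  ss <- structure_set(g, ctv, empty, empty, ln)
  sc <- scalar_features(ss, dummy_record())
  expect_equal(unname(sc["image_resolution"]), 1.1543)
})

test_that("extract_features yields the 110-name schema, invariant to ordering", {
  atlas <- small_atlas(48)
  p <- generate_patient(atlas, effect_spec(), seed = 41)
  fv <- extract_features(p$ss, p$record)
  expect_length(fv, 110)
  expect_identical(names(fv), feature_names())
  expect_true(all(fv[1:96] >= 0 & fv[1:96] <= 1))
  expect_true(all(fv[paste0("overlap_", overlap_flag_stations())] %in% c(0, 1)))
  # shuffling the station list (named) must not change the result
  ss_shuf <- structure_set(p$ss$grid, p$ss$ctv, p$ss$gtv, p$ss$gtvnd,
                           p$ss$ln[sample(16)])
  expect_identical(extract_features(ss_shuf, p$record), fv)
})

test_that("dice matches its closed form and symmetry", {
  g <- small_grid(16, 1)
  a <- array(FALSE, g$shape); a[1:10, 1:10, 1] <- TRUE # 100 voxels
  b <- array(FALSE, g$shape); b[6:15, 1:10, 1] <- TRUE # 100 voxels, 50 shared
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, b), 0.5)
  expect_equal(dice(a, b), dice(b, a))
  disj <- array(FALSE, g$shape); disj[1, 1, 16] <- TRUE
  expect_equal(dice(a, disj), 0)
  empty <- array(FALSE, g$shape)
  expect_equal(dice(empty, empty), 1)
  expect_error(dice(a, array(FALSE, c(2, 2, 2))), class = "ctv_shape_error")
})

test_that("hausdorff distance matches a naive all-pairs oracle", {
  g <- voxel_grid(c(12, 12, 12), c(1.5, 1.5, 1.5))
  a <- array(FALSE, g$shape); a[2, 2, 2] <- TRUE
  b <- array(FALSE, g$shape); b[12, 2, 2] <- TRUE
  expect_equal(hausdorff_mm(a, b, g), 15) # 10 lattice steps at 1.5 mm
  expect_equal(hausdorff_mm(a, a, g), 0)
  expect_error(hausdorff_mm(a, array(FALSE, g$shape), g),
               class = "ctv_empty_mask")

  # random small masks vs a brute-force oracle with loop-built boundaries
  set.seed(77)
  ra <- array(runif(12^3) < 0.05, rep(12, 3))
  rb <- array(runif(12^3) < 0.05, rep(12, 3))
  naive_boundary <- function(m) {
    pts <- NULL
    d <- dim(m)
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
      if (!m[i, j, k]) next
      nb <- c(
        if (i > 1) m[i - 1, j, k] else FALSE,
        if (i < d[1]) m[i + 1, j, k] else FALSE,
        if (j > 1) m[i, j - 1, k] else FALSE,
        if (j < d[2]) m[i, j + 1, k] else FALSE,
        if (k > 1) m[i, j, k - 1] else FALSE,
        if (k < d[3]) m[i, j, k + 1] else FALSE)
      if (!all(nb)) pts <- rbind(pts, c(i, j, k))
    }
    sweep(pts - 1, 2, c(1.5, 1.5, 1.5), `*`)
  }
  dir_h <- function(p, q) {
    max(apply(p, 1, function(x) min(sqrt(colSums((t(q) - x)^2)))))
  }
  pa <- naive_boundary(ra); pb <- naive_boundary(rb)
  expect_equal(hausdorff_mm(ra, rb, g), max(dir_h(pa, pb), dir_h(pb, pa)))
  expect_equal(hausdorff_mm(ra, rb, g), hausdorff_mm(rb, ra, g))
})
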