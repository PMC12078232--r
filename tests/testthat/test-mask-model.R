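test_that("voxel_grid rejects degenerate geometry and computes voxel volume", {
  expect_error(voxel_grid(c(0, 10, 10)), class = "ctv_grid_error")
  expect_error(voxel_grid(c(10, 10, 10), spacing = c(1, -1, 1)),
               class = "ctv_grid_error")
  g <- voxel_grid(c(10, 10, 10), c(1.1543, 1.1543, 5))
  expect_equal(voxel_volume(g), 1.1543^2 * 5)
})

test_that("volume_mm3 counts voxels times voxel volume", {
  g <- voxel_grid(c(10, 10, 10))
  m <- array(FALSE, c(10, 10, 10))
  expect_equal(volume_mm3(m, g), 0)
  m[1:10, 1:10, 1] <- TRUE
  expect_equal(volume_mm3(m, g), 100)
  expect_error(volume_mm3(array(FALSE, c(5, 5, 5)), g),
               class = "ctv_shape_error")
})

test_that("rasterized sphere volume approaches the analytic value", {
  # radius 10 mm sphere at 0.5 mm spacing: within 2% of 4*pi*r^3/3
  g <- voxel_grid(c(50, 50, 50), c(0.5, 0.5, 0.5))
  m <- rasterize_ellipsoid(g, center = c(12.5, 12.5, 12.5), semi_axes = rep(10, 3))
  expect_lt(abs(volume_mm3(m, g) - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.02)
  # convergence: the coarser rasterization errs more than the finer one
  g2 <- voxel_grid(c(13, 13, 13), c(2, 2, 2))
  m2 <- rasterize_ellipsoid(g2, center = c(12, 12, 12), semi_axes = rep(10, 3))
  err2 <- abs(volume_mm3(m2, g2) - 4 / 3 * pi * 1000)
  err1 <- abs(volume_mm3(m, g) - 4 / 3 * pi * 1000)
  expect_lt(err1, err2)
})

test_that("volume is additive over disjoint masks and monotone under inclusion", {
  g <- voxel_grid(c(12, 12, 12), c(1.5, 1.5, 1.5))
  set.seed(11)
  a <- array(runif(12^3) < 0.2, rep(12, 3))
  b <- array(runif(12^3) < 0.2, rep(12, 3)) & !a
  expect_equal(volume_mm3(a, g) + volume_mm3(b, g), volume_mm3(a | b, g))
  expect_lte(volume_mm3(a & b, g), volume_mm3(a, g))
  expect_lte(volume_mm3(a, g), volume_mm3(a | b, g))
})

test_that("validate_structure_set reports overlaps, empties and containment", {
  grid <- box_station_grid()
  ln <- box_station_masks()
  ctv <- box_mask(grid, c(2, 2, 10), c(8, 8, 13))
  empty <- array(FALSE, grid$shape)
  # valid set -> empty report
  ss <- structure_set(grid, ctv, empty, empty, ln, validate = FALSE)
  expect_equal(nrow(validate_structure_set(ss)), 0)

  # one-voxel overlap between stations 3 and 7 is named with its count
  ln_bad <- ln
  vox <- which(ln[[7]])[1]
  ln_bad[[3]][vox] <- TRUE
  ss_bad <- structure_set(grid, ctv, empty, empty, ln_bad, validate = FALSE)
  rep <- validate_structure_set(ss_bad)
  expect_true(any(rep$rule == "ln_overlap" & rep$structures == "LN3,LN7" &
                    rep$count == 1))

  # GTV voxel outside CTV is a containment violation
  gtv <- array(FALSE, grid$shape); gtv[1, 1, 1] <- TRUE
  ss_out <- structure_set(grid, ctv, gtv, empty, ln, validate = FALSE)
  expect_true("gtv_outside_ctv" %in% validate_structure_set(ss_out)$rule)
  expect_error(structure_set(grid, ctv, gtv, empty, ln, validate = TRUE),
               class = "ctv_invalid_structure_set")
})

test_that("structure sets round-trip through NIfTI voxel-exactly", {
  atlas <- small_atlas(32)
  p <- generate_patient(atlas, effect_spec(), seed = 5)
  p$ss$recurrence <- rasterize_ellipsoid(atlas$grid, c(24, 24, 24), c(4, 4, 4))
  dir <- withr::local_tempdir()
  save_structure_set(p$ss, dir, record = p$record)
  back <- load_structure_set(dir)
  expect_identical(back$ss$ctv, p$ss$ctv)
  expect_identical(back$ss$gtv, p$ss$gtv)
  expect_identical(back$ss$gtvnd, p$ss$gtvnd)
  expect_identical(back$ss$recurrence, p$ss$recurrence)
  for (i in 1:16) expect_identical(back$ss$ln[[i]], p$ss$ln[[i]])
  expect_equal(back$ss$grid$spacing, p$ss$grid$spacing)
  expect_equal(back$record$tumor_diameter_cm, p$record$tumor_diameter_cm)
  expect_equal(back$record$relapse, p$record$relapse)
})

test_that("anisotropic spacing survives a save/load round trip exactly", {
  g <- voxel_grid(c(16, 16, 8), c(1.1543, 1.1543, 5))
  ln <- lapply(1:16, function(i) {
    m <- array(FALSE, g$shape); m[((i - 1) %% 16) + 1, (i - 1) %/% 2 + 1, 1] <- TRUE; m
  })
  ctv <- Reduce(`|`, ln)
  empty <- array(FALSE, g$shape)
  ss <- structure_set(g, ctv, empty, empty, ln)
  dir <- withr::local_tempdir()
  save_structure_set(ss, dir)
  back <- load_structure_set(dir)
  expect_identical(back$ss$grid$spacing, c(1.1543, 1.1543, 5))
})

test_that("loading enforces the manifest: missing structures and grid mismatches", {
  atlas <- small_atlas(32)
  p <- generate_patient(atlas, effect_spec(), seed = 6)
  dir <- withr::local_tempdir()
  save_structure_set(p$ss, dir, record = p$record)

  # optional recurrence absent -> no file, reload gives NULL
  expect_false(file.exists(file.path(dir, "recurrence.nii.gz")))
  expect_null(load_structure_set(dir)$ss$recurrence)

  file.remove(file.path(dir, "ctv.nii.gz"))
  expect_error(load_structure_set(dir), "missing structure: CTV",
               class = "ctv_missing_structure")

  # re-save, then corrupt one mask's shape
  save_structure_set(p$ss, dir, record = p$record)
  small <- RNifti::asNifti(array(0L, c(8, 8, 8)))
  RNifti::writeNifti(small, file.path(dir, "ln05.nii.gz"))
  expect_error(load_structure_set(dir), "ln05", class = "ctv_grid_mismatch")
})
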