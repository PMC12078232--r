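# Shared fixtures: cached atlases and a hand-sized box-station structure set
# whose overlaps can be counted on paper.

.fixtures <- new.env(parent = emptyenv())

small_grid <- function(n = 48L, spacing = 1.5) {
  voxel_grid(rep(as.integer(n), 3), rep(spacing, 3))
}

small_atlas <- function(n = 48L, spacing = 1.5) {
  key <- sprintf("atlas_%d_%g", n, spacing)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- generate_atlas(atlas_spec(small_grid(n, spacing)))
  }
  .fixtures[[key]]
}

box_mask <- function(grid, from, to) {
  m <- array(FALSE, grid$shape)
  m[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- TRUE
  m
}

# 16 disjoint 4x4x4 box "stations" tiled 4x4 in one z-slab of a 30^3 grid at
# 1 mm spacing; each station has 64 voxels, so coverage fractions are exact
# dyadic numbers
box_station_grid <- function() voxel_grid(c(30L, 30L, 30L), c(1, 1, 1))

box_station_masks <- function() {
  if (is.null(.fixtures$box_ln)) {
    grid <- box_station_grid()
    ln <- vector("list", 16)
    k <- 0
    for (gy in 0:3) {
      for (gx in 0:3) {
        k <- k + 1
        x0 <- 2 + gx * 7; y0 <- 2 + gy * 7
        ln[[k]] <- box_mask(grid, c(x0, y0, 10), c(x0 + 3, y0 + 3, 13))
      }
    }
    names(ln) <- station_labels()
    .fixtures$box_ln <- ln
  }
  .fixtures$box_ln
}

# structure set on the box-station grid with caller-chosen CTV/GTV/GTVnd
box_structure_set <- function(ctv, gtv = NULL, gtvnd = NULL,
                              recurrence = NULL, validate = TRUE) {
  grid <- box_station_grid()
  empty <- array(FALSE, grid$shape)
  structure_set(grid, ctv = ctv, gtv = gtv %||% empty,
                gtvnd = gtvnd %||% empty, ln = box_station_masks(),
                recurrence = recurrence, validate = validate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

dummy_record <- function(relapse = 0L, lung_area_code = 1L,
                         tumor_diameter_cm = 4) {
  patient_record("fix", 60, "male", "T2", "N2", "III", 200,
                 tumor_diameter_cm, "central", "synchronous",
                 24, relapse, lung_area_code)
}

# brute-force recount of the six ratio families through index sets --
# an independent route from the package's logical-array arithmetic
oracle_ratios <- function(ss, gross = "union") {
  vox <- function(m) which(m)
  ctv <- vox(ss$ctv)
  g <- if (gross == "union") vox(ss$gtv | ss$gtvnd) else vox(ss$gtv)
  ln <- lapply(ss$ln, vox)
  n_int <- function(a, b) length(intersect(a, b))
  ctv_ln <- vapply(ln, n_int, numeric(1), a = ctv)
  g_ln <- vapply(ln, n_int, numeric(1), a = g)
  cmg <- setdiff(ctv, g)
  cmg_ln <- vapply(ln, n_int, numeric(1), a = cmg)
  sizes <- lengths(ln)
  idea <- length(unique(unlist(ln[ctv_ln > 0])))
  ri <- function(x) if (idea > 0) x / idea else rep(0, 16)
  out <- c(ctv_ln / sizes, ri(ctv_ln), g_ln / sizes, ri(g_ln),
           cmg_ln / sizes, ri(cmg_ln))
  names(out) <- feature_names()[1:96]
  out
}
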