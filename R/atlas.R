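#' Specification of a stylized mediastinal station atlas
#'
#' Sixteen ellipsoidal lymph-node stations laid out in a simplified
#' mediastinal arrangement: supraclavicular/upper paratracheal stations
#' (1R/1L above 2R/2L) superiorly, prevascular/retrotracheal (3A anterior,
#' 3P posterior), lower paratracheal (4R/4L), aortopulmonary (5, 6) on the
#' left, subcarinal station 7 centrally, paraesophageal station 8
#' inferiorly, and hilar/interlobar stations (10R/10L, 11R/11L)
#' lateral-inferiorly. The layout is defined in fractions of the grid's
#' physical extent, so the same anatomy scales to any grid size; the
#' default grid is 96^3 voxels at 1.5 mm isotropic spacing (a 144 mm cube).
#'
#' This is a geometric stand-in for anatomically accurate IASLC station
#' boundaries: it preserves the statistical structure the analyses need
#' (disjoint stations of plausible relative size and adjacency), not real
#' anatomy.
#'
#' @param grid a [voxel_grid()]; default 96^3 at 1.5 mm.
#' @param station_centers optional 16 x 3 matrix of mm centres (rows in
#'   [station_labels()] order) overriding the scaled defaults.
#' @param station_radii optional 16 x 3 matrix of mm ellipsoid semi-axes.
#' @param radius_scale multiplier applied to the default semi-axes.
#' @return An object of class `atlas_spec`.
#' @export
atlas_spec <- function(grid = voxel_grid(c(96L, 96L, 96L), c(1.5, 1.5, 1.5)),
                       station_centers = NULL, station_radii = NULL,
                       radius_scale = 1) {
  stopifnot(inherits(grid, "voxel_grid"))
  ext <- grid_extent_mm(grid)
  ref <- 144 # mm extent the canonical layout was designed at
  centers_ref <- matrix(c(
    60, 72, 124,   # 1R
    84, 72, 124,   # 1L
    58, 70, 106,   # 2R
    86, 70, 106,   # 2L
    72, 50, 100,   # 3A
    72, 94, 100,   # 3P
    56, 72, 88,    # 4R
    88, 72, 88,    # 4L
    94, 58, 82,    # 5
    98, 46, 92,    # 6
    72, 72, 72,    # 7
    72, 76, 52,    # 8
    44, 72, 74,    # 10R
    100, 72, 74,   # 10L
    38, 78, 58,    # 11R
    106, 78, 58    # 11L
  ), ncol = 3, byrow = TRUE)
  radii_ref <- matrix(c(
    7, 7, 8,        7, 7, 8,       # 1R 1L
    7, 7, 8,        7, 7, 8,       # 2R 2L
    6, 6, 7,        6, 6, 7,       # 3A 3P
    7, 7, 8,        7, 7, 8,       # 4R 4L
    6, 6, 7,        6, 6, 7,       # 5  6
    8, 8, 8,        6.5, 6.5, 7.5, # 7  8
    7.5, 7.5, 8,    7.5, 7.5, 8,   # 10R 10L
    6.5, 6.5, 7.5,  6.5, 6.5, 7.5  # 11R 11L
  ), ncol = 3, byrow = TRUE)
  scale3 <- function(m) sweep(m, 2, ext / ref, `*`)
  centers <- station_centers %||% (scale3(centers_ref) +
                                     matrix(grid$origin, 16, 3, byrow = TRUE))
  radii <- station_radii %||% (scale3(radii_ref) * radius_scale)
  stopifnot(is.matrix(centers), all(dim(centers) == c(16, 3)),
            is.matrix(radii), all(dim(radii) == c(16, 3)), all(radii > 0))
  rownames(centers) <- rownames(radii) <- station_labels()
  structure(list(grid = grid, station_centers = centers,
                 station_radii = radii),
            class = "atlas_spec")
}

#' Generate the sixteen station masks of an atlas
#'
#' Rasterizes each station ellipsoid onto the grid and enforces the atlas
#' invariants: every station non-empty and all stations pairwise disjoint.
#' The construction is deterministic for a given spec.
#'
#' @param spec an [atlas_spec()].
#' @return list of class `station_atlas` with elements `grid`, `spec` and
#'   `masks` (named list of 16 logical arrays in [station_labels()] order).
#' @export
generate_atlas <- function(spec = atlas_spec()) {
  stopifnot(inherits(spec, "atlas_spec"))
  labs <- station_labels()
  masks <- lapply(1:16, function(i) {
    rasterize_ellipsoid(spec$grid, spec$station_centers[i, ],
                        spec$station_radii[i, ])
  })
  names(masks) <- labs
  empty <- !vapply(masks, any, logical(1))
  if (any(empty)) {
    ctv_stop("ctv_atlas_error", "station mask(s) empty on this grid: %s",
             paste(labs[empty], collapse = ", "))
  }
  occupancy <- Reduce(`+`, lapply(masks, function(m) m + 0L))
  if (any(occupancy > 1L)) {
    for (i in 1:15) {
      for (j in (i + 1):16) {
        if (any(masks[[i]] & masks[[j]])) {
          ctv_stop("ctv_atlas_error",
                   "station ellipsoids %s and %s overlap on the grid",
                   labs[i], labs[j])
        }
      }
    }
  }
  structure(list(grid = spec$grid, spec = spec, masks = masks),
            class = "station_atlas")
}
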