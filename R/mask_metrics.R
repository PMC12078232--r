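#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty (two
#' empty delineations agree perfectly).
#'
#' @param a,b logical/0-1 arrays of identical shape.
#' @return number in `[0, 1]`.
#' @export
#' @examples
#' m <- array(c(TRUE, FALSE), c(2, 1, 1))
#' dice(m, m) # 1
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    ctv_stop("ctv_shape_error", "dice: masks have different shapes")
  }
  na <- sum(a != 0); nb <- sum(b != 0)
  if (na + nb == 0) return(1)
  2 * sum(a != 0 & b != 0) / (na + nb)
}

#' Symmetric Hausdorff distance between two masks, in mm
#'
#' The maximum over both directions of the largest distance from a boundary
#' voxel centre of one mask to the nearest boundary voxel centre of the
#' other, with voxel offsets scaled by the grid spacing. Boundary voxels are
#' mask voxels with at least one 6-neighbour outside the mask (voxels on the
#' grid edge count as boundary).
#'
#' @param a,b non-empty logical masks on the same grid.
#' @param grid a [voxel_grid()].
#' @return distance in mm (0 for identical masks).
#' @export
hausdorff_mm <- function(a, b, grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!identical(dim(a), dim(b))) {
    ctv_stop("ctv_shape_error", "hausdorff_mm: masks have different shapes")
  }
  if (!any(a != 0) || !any(b != 0)) {
    ctv_stop("ctv_empty_mask", "hausdorff_mm is undefined for empty masks")
  }
  pa <- boundary_coords_mm(a != 0, grid)
  pb <- boundary_coords_mm(b != 0, grid)
  max(directed_hausdorff(pa, pb), directed_hausdorff(pb, pa))
}

# mm coordinates of boundary voxel centres (n x 3 matrix)
boundary_coords_mm <- function(mask, grid) {
  d <- dim(mask)
  interior <- array(TRUE, d)
  shift_ok <- function(ax, by) {
    # TRUE where the neighbour at offset `by` along axis `ax` is inside mask
    out <- array(FALSE, d)
    idx_src <- vector("list", 3); idx_dst <- vector("list", 3)
    for (k in 1:3) idx_src[[k]] <- idx_dst[[k]] <- seq_len(d[k])
    if (by > 0) { idx_dst[[ax]] <- 1:(d[ax] - 1); idx_src[[ax]] <- 2:d[ax] }
    else { idx_dst[[ax]] <- 2:d[ax]; idx_src[[ax]] <- 1:(d[ax] - 1) }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      mask[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (ax in 1:3) {
    interior <- interior & shift_ok(ax, +1) & shift_ok(ax, -1)
  }
  boundary <- mask & !interior
  idx <- which(boundary, arr.ind = TRUE)
  cbind(grid$origin[1] + (idx[, 1] - 1) * grid$spacing[1],
        grid$origin[2] + (idx[, 2] - 1) * grid$spacing[2],
        grid$origin[3] + (idx[, 3] - 1) * grid$spacing[3])
}

# max over rows of A of the min distance to rows of B, chunked to bound memory
directed_hausdorff <- function(pa, pb, chunk = 512L) {
  worst <- 0
  nb <- nrow(pb)
  for (start in seq(1L, nrow(pa), by = chunk)) {
    rows <- start:min(start + chunk - 1L, nrow(pa))
    d2 <- outer(pa[rows, 1], pb[, 1], "-")^2 +
      outer(pa[rows, 2], pb[, 2], "-")^2 +
      outer(pa[rows, 3], pb[, 3], "-")^2
    worst <- max(worst, max(apply(d2, 1, min)))
  }
  sqrt(worst)
}
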