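#' Voxel grid geometry
#'
#' Describes the shared 3D lattice all masks of a structure set live on:
#' number of voxels per axis, voxel edge lengths in mm, and the mm
#' coordinate of the first voxel centre. Axis order is (x, y, z) with
#' 0-based voxel indices, so voxel `(i, j, k)` (0-based) has centre
#' `origin + c(i, j, k) * spacing`. All masks must be pre-resampled to this
#' grid; no on-the-fly resampling is performed anywhere in the package.
#'
#' @param shape integer length-3, voxels per axis (each >= 1).
#' @param spacing numeric length-3, voxel edge lengths in mm (each > 0).
#' @param origin numeric length-3, mm coordinate of voxel (0,0,0); default 0.
#' @return An object of class `voxel_grid`.
#' @export
#' @examples
#' g <- voxel_grid(c(96, 96, 96), spacing = c(1.5, 1.5, 1.5))
#' voxel_volume(g) # 3.375 mm^3
voxel_grid <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(shape) != 3L || anyNA(shape) || any(shape < 1L)) {
    ctv_stop("ctv_grid_error", "shape must be 3 integers >= 1")
  }
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0)) {
    ctv_stop("ctv_grid_error", "spacing must be 3 positive numbers (mm)")
  }
  if (length(origin) != 3L || anyNA(origin)) {
    ctv_stop("ctv_grid_error", "origin must be 3 finite numbers (mm)")
  }
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid %d x %d x %d, spacing %.4g x %.4g x %.4g mm>\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' @rdname voxel_grid
#' @param grid a `voxel_grid`.
#' @export
voxel_volume <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  prod(grid$spacing)
}

#' Physical extent of a grid in mm
#' @inheritParams voxel_volume
#' @return numeric length-3, `shape * spacing`.
#' @export
grid_extent_mm <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  grid$shape * grid$spacing
}

# mm coordinates of every voxel centre along one axis (1-based R index i
# maps to 0-based voxel index i-1)
axis_coords <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 1) * grid$spacing[axis]
}

same_shape <- function(mask, grid) {
  identical(dim(mask), grid$shape) ||
    identical(as.integer(dim(mask)), grid$shape)
}

#' Mask volume in cubic millimetres
#'
#' Volume is the voxel count times the voxel volume; a voxel belongs to a
#' structure iff its mask value is set (no partial-volume weighting).
#'
#' @param mask logical/0-1 array with the grid's shape.
#' @param grid a [voxel_grid()].
#' @return volume in mm^3 (0 for an empty mask).
#' @export
#' @examples
#' g <- voxel_grid(c(10, 10, 10))
#' m <- array(FALSE, c(10, 10, 10)); m[1:10, 1, 1] <- TRUE
#' volume_mm3(m, g) # 10
volume_mm3 <- function(mask, grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!same_shape(mask, grid)) {
    ctv_stop("ctv_shape_error",
             "mask shape (%s) does not match grid shape (%s)",
             paste(dim(mask), collapse = "x"),
             paste(grid$shape, collapse = "x"))
  }
  sum(mask != 0) * voxel_volume(grid)
}

#' Rasterize an axis-aligned ellipsoid onto a grid
#'
#' A voxel is inside iff its centre satisfies the ellipsoid inequality.
#' Disjoint continuous ellipsoids therefore always rasterize to disjoint
#' masks (a voxel centre cannot lie in two disjoint solids).
#'
#' @param grid a [voxel_grid()].
#' @param center mm length-3 centre.
#' @param semi_axes mm length-3 positive semi-axes.
#' @return logical array of the grid's shape.
#' @export
rasterize_ellipsoid <- function(grid, center, semi_axes) {
  stopifnot(inherits(grid, "voxel_grid"),
            length(center) == 3L, length(semi_axes) == 3L,
            all(semi_axes > 0))
  dx2 <- ((axis_coords(grid, 1) - center[1]) / semi_axes[1])^2
  dy2 <- ((axis_coords(grid, 2) - center[2]) / semi_axes[2])^2
  dz2 <- ((axis_coords(grid, 3) - center[3]) / semi_axes[3])^2
  q <- outer(outer(dx2, dy2, "+"), dz2, "+")
  q <= 1
}

#' Dilate a binary mask by a Euclidean ball
#'
#' Morphological dilation with a ball of radius `margin_mm`, computed by FFT
#' convolution with the ball's indicator on a zero-padded grid (exact: it
#' reproduces the union-of-shifts definition voxel for voxel). Used to grow
#' gross disease into a clinical target volume.
#'
#' @param mask logical array.
#' @param grid a [voxel_grid()] (supplies anisotropic spacing).
#' @param margin_mm dilation radius in mm; `0` returns the mask unchanged.
#' @return logical array of the same shape.
#' @export
dilate_mask <- function(mask, grid, margin_mm) {
  stopifnot(inherits(grid, "voxel_grid"), margin_mm >= 0)
  if (!same_shape(mask, grid)) {
    ctv_stop("ctv_shape_error", "mask shape does not match grid shape")
  }
  if (margin_mm == 0 || !any(mask)) return(mask != 0)
  dims <- grid$shape
  sp <- grid$spacing
  rad <- pmax(ceiling(margin_mm / sp), 1L)
  pd <- dims + 2L * rad
  # ball indicator centred at the origin of the padded torus
  ax <- lapply(1:3, function(k) {
    i <- 0:(pd[k] - 1L)
    (pmin(i, pd[k] - i) * sp[k])^2
  })
  kern <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+") <= margin_mm^2
  padded <- array(0, pd)
  padded[seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3])] <- mask != 0
  conv <- Re(fft(fft(padded) * fft(kern + 0), inverse = TRUE)) / prod(pd)
  conv[seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3])] > 0.5
}
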