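#' Canonical names of the 110 partition parameters
#'
#' Ninety-six station overlap ratios (six families of sixteen) followed by
#' fourteen scalar parameters, in the fixed schema order used everywhere in
#' the package:
#'
#' * 1-16 `RctvLN1..16` — fraction of each station's volume covered by the CTV
#' * 17-32 `RIctvLN1..16` — each CTV-station overlap as a fraction of the
#'   ideal CTV volume
#' * 33-48 `RgtvLN1..16` — fraction of each station covered by gross disease
#' * 49-64 `RIgtvLN1..16` — gross-disease-station overlap / ideal CTV
#' * 65-80 `RcmgLN1..16` — fraction of each station covered by CTV minus
#'   gross disease
#' * 81-96 `RIcmgLN1..16` — (CTV minus gross disease)-station overlap /
#'   ideal CTV
#' * 97-110 `ctv_volume`, `gtvnd_volume`, `image_resolution`, `n_ln_ctv`,
#'   `n_ln_gtvnd`, `lung_area_code`, `overlap_4L`, `overlap_4R`, `overlap_5`,
#'   `overlap_6`, `overlap_7`, `overlap_11L`, `overlap_11R`, `gtv_size`
#'
#' @return character vector of length 110.
#' @export
feature_names <- function() {
  c(paste0("RctvLN", 1:16), paste0("RIctvLN", 1:16),
    paste0("RgtvLN", 1:16), paste0("RIgtvLN", 1:16),
    paste0("RcmgLN", 1:16), paste0("RIcmgLN", 1:16),
    "ctv_volume", "gtvnd_volume", "image_resolution",
    "n_ln_ctv", "n_ln_gtvnd", "lung_area_code",
    paste0("overlap_", overlap_flag_stations()), "gtv_size")
}

# gross-disease mask used by the ratio families: all gross disease (primary
# plus nodal) by default, primary tumor only on request
gross_mask <- function(ss, gross_disease = c("union", "primary_only")) {
  gross_disease <- match.arg(gross_disease)
  if (gross_disease == "union") ss$gtv | ss$gtvnd else ss$gtv
}

#' The ideal CTV: union of all stations touched by the CTV
#'
#' A station is "touched" (violated) when the delineated CTV overlaps it in
#' at least `min_overlap_voxels` voxels; the ideal CTV is the union of the
#' *full* masks of every touched station — overlapping a single voxel of a
#' station pulls the whole station in. It is the normalising volume for the
#' `RI*` ratio families and represents the target a delineation aiming to
#' cover every violated station completely would have used.
#'
#' @param ss a [structure_set()].
#' @param min_overlap_voxels minimum CTV-station overlap (voxels) for a
#'   station to count as touched; default 1 (any overlap).
#' @return logical mask (empty when the CTV touches no station).
#' @export
idea_ctv <- function(ss, min_overlap_voxels = 1L) {
  stopifnot(inherits(ss, "structure_set"), min_overlap_voxels >= 1L)
  touched <- touched_stations(ss, min_overlap_voxels)
  out <- array(FALSE, dim = ss$grid$shape)
  for (i in which(touched)) out <- out | ss$ln[[i]]
  out
}

touched_stations <- function(ss, min_overlap_voxels = 1L) {
  vapply(ss$ln, function(m) sum(ss$ctv & m) >= min_overlap_voxels, logical(1))
}

#' The six station overlap ratio families (96 ratios)
#'
#' For each station `i` in 1..16, with `G` the gross-disease mask and
#' `|.|` voxel counts (voxel volume cancels in every ratio):
#' `RctvLNi = |CTV n LNi| / |LNi|`,
#' `RIctvLNi = |CTV n LNi| / |ideaCTV|`,
#' `RgtvLNi = |G n LNi| / |LNi|`,
#' `RIgtvLNi = |G n LNi| / |ideaCTV|`,
#' `RcmgLNi = |(CTV - G) n LNi| / |LNi|`,
#' `RIcmgLNi = |(CTV - G) n LNi| / |ideaCTV|`.
#'
#' When the CTV touches no station the ideal CTV is empty; the `RI*`
#' ratios are then defined as 0 (with a warning) so feature matrices stay
#' numeric.
#'
#' @inheritParams idea_ctv
#' @param gross_disease which masks constitute gross disease `G` in the
#'   GTV-family ratios: `"union"` (GTV plus GTVnd, default) or
#'   `"primary_only"`.
#' @return named numeric vector of length 96 in schema order.
#' @export
ratio_families <- function(ss, gross_disease = c("union", "primary_only"),
                           min_overlap_voxels = 1L) {
  stopifnot(inherits(ss, "structure_set"))
  g <- gross_mask(ss, gross_disease)
  ln_sizes <- vapply(ss$ln, sum, numeric(1))
  if (any(ln_sizes == 0)) {
    ctv_stop("ctv_invalid_structure_set",
             "empty station mask(s): %s",
             paste(station_labels()[ln_sizes == 0], collapse = ", "))
  }
  ctv_ln <- vapply(ss$ln, function(m) sum(ss$ctv & m), numeric(1))
  g_ln <- vapply(ss$ln, function(m) sum(g & m), numeric(1))
  cmg_ln <- vapply(ss$ln, function(m) sum(ss$ctv & !g & m), numeric(1))
  touched <- ctv_ln >= min_overlap_voxels
  idea_size <- sum(ln_sizes[touched]) # stations are disjoint
  if (idea_size == 0) {
    warning("CTV touches no lymph-node station; RI* ratios set to 0",
            call. = FALSE)
    ri <- function(x) rep(0, 16)
  } else {
    ri <- function(x) x / idea_size
  }
  out <- c(ctv_ln / ln_sizes, ri(ctv_ln),
           g_ln / ln_sizes, ri(g_ln),
           cmg_ln / ln_sizes, ri(cmg_ln))
  names(out) <- feature_names()[1:96]
  out
}

#' The fourteen scalar parameters (schema rows 97-110)
#'
#' CTV and GTVnd volumes (mm^3), in-plane image resolution (mm), counts of
#' stations involved by the CTV and by GTVnd, the lung-area quadrant code,
#' seven binary CTV overlap flags for stations 4L, 4R, 5, 6, 7, 11L, 11R,
#' and the pre-treatment tumor size from the clinical record.
#'
#' @inheritParams ratio_families
#' @param record a [patient_record()] supplying `lung_area_code` and tumor
#'   size.
#' @return named numeric vector of length 14.
#' @export
scalar_features <- function(ss, record, min_overlap_voxels = 1L) {
  stopifnot(inherits(ss, "structure_set"), inherits(record, "patient_record"))
  touched <- touched_stations(ss, min_overlap_voxels)
  gtvnd_touch <- vapply(ss$ln, function(m) sum(ss$gtvnd & m) >= min_overlap_voxels,
                        logical(1))
  flags <- as.numeric(touched[ln_index(overlap_flag_stations())])
  out <- c(
    volume_mm3(ss$ctv, ss$grid),
    volume_mm3(ss$gtvnd, ss$grid),
    ss$grid$spacing[1],
    sum(touched),
    sum(gtvnd_touch),
    record$lung_area_code,
    flags,
    record$tumor_diameter_cm
  )
  names(out) <- feature_names()[97:110]
  out
}

#' Extract the full 110-parameter feature vector
#'
#' Concatenates [ratio_families()] (96 ratios) and [scalar_features()]
#' (14 scalars) in schema order.
#'
#' @inheritParams scalar_features
#' @inheritParams ratio_families
#' @return named numeric vector of length 110.
#' @export
extract_features <- function(ss, record,
                             gross_disease = c("union", "primary_only"),
                             min_overlap_voxels = 1L) {
  c(ratio_families(ss, gross_disease, min_overlap_voxels),
    scalar_features(ss, record, min_overlap_voxels))
}

#' Extract a cohort feature matrix
#'
#' @param cohort a list as returned by [generate_cohort()] (elements `ss`,
#'   `record`), or any list of `list(ss=, record=)` pairs.
#' @inheritParams extract_features
#' @return data frame with an `id` column, the 110 feature columns and a
#'   `relapse` column.
#' @export
extract_cohort_features <- function(cohort,
                                    gross_disease = c("union", "primary_only"),
                                    min_overlap_voxels = 1L) {
  patients <- if (!is.null(cohort$patients)) cohort$patients else cohort
  rows <- lapply(patients, function(p) {
    extract_features(p$ss, p$record, gross_disease, min_overlap_voxels)
  })
  X <- do.call(rbind, rows)
  out <- data.frame(
    id = vapply(patients, function(p) p$record$id, character(1)),
    X,
    relapse = vapply(patients, function(p) p$record$relapse, integer(1)),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  rownames(out) <- NULL
  out
}
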