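#' Build a structure set
#'
#' A structure set bundles the co-registered binary masks of one patient on
#' one shared [voxel_grid()]: the delineated clinical target volume (CTV),
#' the primary gross tumor volume (GTV), nodal gross disease (GTVnd), an
#' optional recurrence region, and the 16 lymph-node station masks.
#'
#' @param grid a [voxel_grid()].
#' @param ctv,gtv,gtvnd logical/0-1 arrays with the grid's shape.
#' @param ln list of 16 station masks in [station_labels()] order (may be
#'   named by label; names are checked when present).
#' @param recurrence optional recurrence mask (`NULL` when absent).
#' @param validate run [validate_structure_set()] and fail on violations?
#' @return An object of class `structure_set`.
#' @seealso [validate_structure_set()], [load_structure_set()]
#' @export
structure_set <- function(grid, ctv, gtv, gtvnd, ln, recurrence = NULL,
                          validate = TRUE) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!is.list(ln) || length(ln) != 16L) {
    ctv_stop("ctv_structure_error", "ln must be a list of 16 station masks")
  }
  if (!is.null(names(ln)) && !identical(names(ln), station_labels())) {
    ln <- ln[station_labels()]
    if (any(vapply(ln, is.null, logical(1)))) {
      ctv_stop("ctv_structure_error",
               "named ln list must contain every station label exactly once")
    }
  }
  names(ln) <- station_labels()
  as_mask <- function(m) {
    storage.mode(m) <- "logical"
    m
  }
  ss <- structure(list(
    grid = grid,
    ctv = as_mask(ctv),
    gtv = as_mask(gtv),
    gtvnd = as_mask(gtvnd),
    recurrence = if (is.null(recurrence)) NULL else as_mask(recurrence),
    ln = lapply(ln, as_mask)
  ), class = "structure_set")
  shapes_ok <- vapply(all_masks(ss), function(m) same_shape(m, grid), logical(1))
  if (!all(shapes_ok)) {
    ctv_stop("ctv_grid_mismatch",
             "masks do not all share the grid shape; offending: %s",
             paste(names(shapes_ok)[!shapes_ok], collapse = ", "))
  }
  if (validate) {
    rep <- validate_structure_set(ss)
    if (nrow(rep) > 0L) {
      ctv_stop("ctv_invalid_structure_set", "invalid structure set:\n%s",
               paste(sprintf("- %s: %s", rep$rule, rep$detail), collapse = "\n"))
    }
  }
  ss
}

# named list of every present mask (stations as LN labels)
all_masks <- function(ss) {
  m <- c(list(ctv = ss$ctv, gtv = ss$gtv, gtvnd = ss$gtvnd), ss$ln)
  if (!is.null(ss$recurrence)) m$recurrence <- ss$recurrence
  m
}

#' @export
print.structure_set <- function(x, ...) {
  vols <- vapply(x$ln, sum, numeric(1))
  cat(sprintf(
    "<structure_set on %dx%dx%d grid: CTV %d vox, GTV %d vox, GTVnd %d vox, %d/16 stations non-empty%s>\n",
    x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
    sum(x$ctv), sum(x$gtv), sum(x$gtvnd), sum(vols > 0),
    if (is.null(x$recurrence)) "" else sprintf(", recurrence %d vox", sum(x$recurrence))
  ))
  invisible(x)
}

#' Validate structure-set invariants
#'
#' Checks, without stopping, the three invariants every analysis in the
#' package relies on: pairwise disjoint station masks (the ratio formulas
#' double-count under overlap, so overlap is an error, never auto-repaired),
#' non-empty station masks, and CTV containment of gross disease
#' (GTV and GTVnd are subsets of the CTV).
#'
#' @param ss a [structure_set()].
#' @return A data frame report with columns `rule`, `structures`, `count`,
#'   `detail`; zero rows iff the set is valid.
#' @export
validate_structure_set <- function(ss) {
  stopifnot(inherits(ss, "structure_set"))
  rules <- character(); structs <- character(); counts <- integer(); details <- character()
  add <- function(rule, st, n, detail) {
    rules <<- c(rules, rule); structs <<- c(structs, st)
    counts <<- c(counts, n); details <<- c(details, detail)
  }
  labs <- station_labels()
  # station disjointness, reported pairwise so the offending pair is named
  occupancy <- Reduce(`+`, lapply(ss$ln, function(m) m + 0L))
  if (any(occupancy > 1L)) {
    for (i in 1:15) {
      for (j in (i + 1):16) {
        n <- sum(ss$ln[[i]] & ss$ln[[j]])
        if (n > 0L) {
          add("ln_overlap", sprintf("LN%d,LN%d", i, j), n,
              sprintf("stations %s and %s share %d voxel(s)", labs[i], labs[j], n))
        }
      }
    }
  }
  for (i in 1:16) {
    if (!any(ss$ln[[i]])) {
      add("ln_empty", sprintf("LN%d", i), 0L,
          sprintf("station %s mask is empty", labs[i]))
    }
  }
  n_out <- sum(ss$gtv & !ss$ctv)
  if (n_out > 0L) {
    add("gtv_outside_ctv", "GTV", n_out,
        sprintf("%d GTV voxel(s) outside CTV", n_out))
  }
  n_out <- sum(ss$gtvnd & !ss$ctv)
  if (n_out > 0L) {
    add("gtvnd_outside_ctv", "GTVnd", n_out,
        sprintf("%d GTVnd voxel(s) outside CTV", n_out))
  }
  data.frame(rule = rules, structures = structs, count = counts,
             detail = details, stringsAsFactors = FALSE)
}

#' Clinical covariate record of one patient
#'
#' @param id patient identifier.
#' @param age_years age in years.
#' @param sex `"male"` or `"female"`.
#' @param t_stage `"T1"`..`"T4"`; `n_stage` `"N0"`..`"N3"`;
#'   `tnm_stage` `"I"`..`"IV"`.
#' @param n_stage,tnm_stage see `t_stage`.
#' @param smoking_index cumulative pack-based smoking exposure (>= 0).
#' @param tumor_diameter_cm greatest tumor diameter in cm (> 0).
#' @param tumor_location `"central"` or `"peripheral"`.
#' @param chemo chemotherapy sequencing, `"synchronous"` or `"sequential"`.
#' @param followup_months observed follow-up time in months (>= 0).
#' @param relapse 0/1 local recurrence label.
#' @param lung_area_code GTV quadrant code 1-4 (1 = right-upper,
#'   2 = right-lower, 3 = left-upper, 4 = left-lower, by GTV centroid).
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(id, age_years, sex, t_stage, n_stage, tnm_stage,
                           smoking_index, tumor_diameter_cm, tumor_location,
                           chemo, followup_months, relapse, lung_area_code) {
  chk <- function(x, allowed, what) {
    x <- as.character(x)
    if (!x %in% allowed) {
      ctv_stop("ctv_record_error", "%s must be one of %s (got '%s')",
               what, paste(allowed, collapse = ", "), x)
    }
    x
  }
  if (smoking_index < 0) ctv_stop("ctv_record_error", "smoking_index must be >= 0")
  if (tumor_diameter_cm <= 0) ctv_stop("ctv_record_error", "tumor_diameter_cm must be > 0")
  if (followup_months < 0) ctv_stop("ctv_record_error", "followup_months must be >= 0")
  if (!relapse %in% c(0, 1)) ctv_stop("ctv_record_error", "relapse must be 0 or 1")
  if (!lung_area_code %in% 1:4) ctv_stop("ctv_record_error", "lung_area_code must be 1..4")
  structure(list(
    id = as.character(id),
    age_years = as.numeric(age_years),
    sex = chk(sex, c("male", "female"), "sex"),
    t_stage = chk(t_stage, paste0("T", 1:4), "t_stage"),
    n_stage = chk(n_stage, paste0("N", 0:3), "n_stage"),
    tnm_stage = chk(tnm_stage, c("I", "II", "III", "IV"), "tnm_stage"),
    smoking_index = as.numeric(smoking_index),
    tumor_diameter_cm = as.numeric(tumor_diameter_cm),
    tumor_location = chk(tumor_location, c("central", "peripheral"), "tumor_location"),
    chemo = chk(chemo, c("synchronous", "sequential"), "chemo"),
    followup_months = as.numeric(followup_months),
    relapse = as.integer(relapse),
    lung_area_code = as.integer(lung_area_code)
  ), class = "patient_record")
}
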