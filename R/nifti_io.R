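#' Structure-set input/output
#'
#' A structure set is stored as one single-channel NIfTI volume per
#' structure (values 0/1, datatype uint8) plus a `patient.json` sidecar
#' holding the grid metadata (shape, spacing, origin), the patient record
#' and the station index/label map. File names follow a configurable
#' manifest; the default is `ctv.nii.gz`, `gtv.nii.gz`, `gtvnd.nii.gz`,
#' `recurrence.nii.gz` (only when a recurrence mask is present) and
#' `ln01.nii.gz` .. `ln16.nii.gz`.
#'
#' `load_structure_set(save_structure_set(ss, d), d)` reproduces every mask
#' voxel-exactly and the grid metadata to full precision.
#'
#' @param ss a [structure_set()].
#' @param path directory to write to / read from (created if missing).
#' @param record optional [patient_record()] stored in the sidecar.
#' @param naming named character vector overriding default file names for
#'   any of `ctv`, `gtv`, `gtvnd`, `recurrence`.
#' @return `save_structure_set()` invisibly returns the written file paths;
#'   `load_structure_set()` returns a list with elements `ss` (validated
#'   [structure_set()]) and `record` ([patient_record()] or `NULL`).
#' @export
save_structure_set <- function(ss, path, record = NULL, naming = NULL) {
  stopifnot(inherits(ss, "structure_set"))
  nm <- io_manifest(naming)
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(path)) {
      ctv_stop("ctv_io_error", "cannot create directory '%s'", path)
    }
  }
  write_one <- function(mask, file) {
    arr <- array(as.integer(mask), dim = ss$grid$shape)
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- ss$grid$spacing
    RNifti::writeNifti(img, file.path(path, file), datatype = "uint8")
    file.path(path, file)
  }
  written <- c(
    write_one(ss$ctv, nm[["ctv"]]),
    write_one(ss$gtv, nm[["gtv"]]),
    write_one(ss$gtvnd, nm[["gtvnd"]]),
    vapply(1:16, function(i) write_one(ss$ln[[i]], sprintf("ln%02d.nii.gz", i)),
           character(1))
  )
  if (!is.null(ss$recurrence)) {
    written <- c(written, write_one(ss$recurrence, nm[["recurrence"]]))
  }
  sidecar <- list(
    grid = list(shape = ss$grid$shape, spacing = ss$grid$spacing,
                origin = ss$grid$origin),
    station_map = station_labels(),
    has_recurrence = !is.null(ss$recurrence)
  )
  if (!is.null(record)) sidecar$patient <- unclass(record)
  jsonlite::write_json(sidecar, file.path(path, "patient.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(written, file.path(path, "patient.json")))
}

#' @rdname save_structure_set
#' @export
load_structure_set <- function(path, naming = NULL) {
  nm <- io_manifest(naming)
  sidecar_file <- file.path(path, "patient.json")
  if (!file.exists(sidecar_file)) {
    ctv_stop("ctv_io_error", "missing sidecar: patient.json in '%s'", path)
  }
  sc <- jsonlite::read_json(sidecar_file, simplifyVector = TRUE)
  grid <- voxel_grid(sc$grid$shape, sc$grid$spacing, sc$grid$origin)

  files <- c(setNames(nm[c("ctv", "gtv", "gtvnd")], c("CTV", "GTV", "GTVnd")),
             setNames(sprintf("ln%02d.nii.gz", 1:16),
                      paste0("LN", 1:16)))
  missing <- !file.exists(file.path(path, files))
  if (any(missing)) {
    ctv_stop("ctv_missing_structure", "missing structure: %s",
             paste(names(files)[missing], collapse = ", "))
  }
  read_one <- function(file) {
    img <- RNifti::readNifti(file.path(path, file))
    arr <- array(as.logical(as.array(img) != 0), dim = dim(img))
    list(mask = arr, shape = as.integer(dim(img)))
  }
  loaded <- lapply(files, read_one)
  shapes <- vapply(loaded, function(x) paste(x$shape, collapse = "x"), character(1))
  ref <- paste(grid$shape, collapse = "x")
  if (any(shapes != ref)) {
    bad <- files[shapes != ref]
    ctv_stop("ctv_grid_mismatch",
             "grid mismatch: expected %s; offending files: %s", ref,
             paste(sprintf("%s (%s)", bad, shapes[shapes != ref]), collapse = ", "))
  }
  recurrence <- NULL
  rec_file <- file.path(path, nm[["recurrence"]])
  if (isTRUE(sc$has_recurrence) || file.exists(rec_file)) {
    if (!file.exists(rec_file)) {
      ctv_stop("ctv_missing_structure", "missing structure: recurrence")
    }
    rec <- read_one(nm[["recurrence"]])
    if (paste(rec$shape, collapse = "x") != ref) {
      ctv_stop("ctv_grid_mismatch",
               "grid mismatch: expected %s; offending files: %s",
               ref, nm[["recurrence"]])
    }
    recurrence <- rec$mask
  }
  ss <- structure_set(
    grid, ctv = loaded[["CTV"]]$mask, gtv = loaded[["GTV"]]$mask,
    gtvnd = loaded[["GTVnd"]]$mask,
    ln = setNames(lapply(paste0("LN", 1:16), function(k) loaded[[k]]$mask),
                  station_labels()),
    recurrence = recurrence
  )
  record <- NULL
  if (!is.null(sc$patient)) {
    p <- sc$patient
    record <- patient_record(p$id, p$age_years, p$sex, p$t_stage, p$n_stage,
                             p$tnm_stage, p$smoking_index, p$tumor_diameter_cm,
                             p$tumor_location, p$chemo, p$followup_months,
                             p$relapse, p$lung_area_code)
  }
  list(ss = ss, record = record)
}

io_manifest <- function(naming = NULL) {
  nm <- c(ctv = "ctv.nii.gz", gtv = "gtv.nii.gz", gtvnd = "gtvnd.nii.gz",
          recurrence = "recurrence.nii.gz")
  if (!is.null(naming)) nm[names(naming)] <- naming
  nm
}
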