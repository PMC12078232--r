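#' Map a recurrence mask to station-level events
#'
#' Each station intersected by the patient's recurrence mask yields one
#' event, so one recurrence region straddling k stations produces k events
#' (cohort event totals therefore exceed patient counts). An event is
#' *GTV-affected* when the recurrence intersects gross disease (GTV or
#' GTVnd) within that station, otherwise it is a *CTV-minus-GTV* event;
#' gross-disease contact takes precedence, so the two classes are mutually
#' exclusive per event. `actual_over_idea` records, for the event's
#' station, the fraction of the ideal station volume actually covered by
#' the delineated CTV (`|CTV n LN_s| / |LN_s|`) — a measure of how
#' completely the violated station was included in the target.
#'
#' Recurrence voxels outside every station are counted and reported in the
#' `out_of_atlas_voxels` attribute, not as events.
#'
#' @param ss a [structure_set()] with a non-empty recurrence mask.
#' @param patient_id identifier stamped on the events.
#' @inheritParams ratio_families
#' @return data frame of class `recurrence_events` with columns
#'   `patient_id`, `station_label`, `gtv_affected`, `actual_over_idea`
#'   (zero rows if the recurrence lies outside all stations).
#' @export
classify_recurrence <- function(ss, patient_id = "p",
                                gross_disease = c("union", "primary_only")) {
  stopifnot(inherits(ss, "structure_set"))
  if (is.null(ss$recurrence) || !any(ss$recurrence)) {
    ctv_stop("ctv_no_recurrence", "no recurrence to classify")
  }
  g <- gross_mask(ss, gross_disease)
  labs <- station_labels()
  rows <- lapply(1:16, function(i) {
    n_hit <- sum(ss$recurrence & ss$ln[[i]])
    if (n_hit == 0) return(NULL)
    data.frame(
      patient_id = patient_id,
      station_label = labs[i],
      gtv_affected = as.integer(sum(ss$recurrence & g & ss$ln[[i]]) > 0),
      actual_over_idea = sum(ss$ctv & ss$ln[[i]]) / sum(ss$ln[[i]]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out) || !is.data.frame(out)) {
    out <- data.frame(patient_id = character(), station_label = character(),
                      gtv_affected = integer(), actual_over_idea = numeric(),
                      stringsAsFactors = FALSE)
  }
  attr(out, "out_of_atlas_voxels") <-
    sum(ss$recurrence & !Reduce(`|`, ss$ln))
  class(out) <- c("recurrence_events", "data.frame")
  out
}

#' @rdname classify_recurrence
#' @param cohort a `ctv_cohort` (patients without a recurrence mask are
#'   skipped).
#' @export
classify_cohort_recurrences <- function(cohort,
                                        gross_disease = c("union", "primary_only")) {
  patients <- if (!is.null(cohort$patients)) cohort$patients else cohort
  rows <- lapply(patients, function(p) {
    if (is.null(p$ss$recurrence) || !any(p$ss$recurrence)) return(NULL)
    classify_recurrence(p$ss, p$record$id, gross_disease)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out) || !is.data.frame(out)) {
    out <- classify_empty_events()
  }
  class(out) <- c("recurrence_events", "data.frame")
  out
}

classify_empty_events <- function() {
  data.frame(patient_id = character(), station_label = character(),
             gtv_affected = integer(), actual_over_idea = numeric(),
             stringsAsFactors = FALSE)
}

#' Reconstruct an event list from printed per-station counts
#'
#' Inverse-of-aggregation helper for re-analysing published station
#' tallies: given per-station event counts with their GTV-affected /
#' CTV-minus-GTV split and the station's mean covered proportion, builds a
#' flat event list whose [tally_by_station()] reproduces the counts exactly
#' and the means to printed precision (the within-station range cannot be
#' reconstructed from a mean and is not).
#'
#' @param counts data frame with columns `station_label`, `n_events`,
#'   `n_gtv_affected` and optionally `mean_actual_over_idea`.
#' @return a `recurrence_events` data frame.
#' @seealso [recurrence_tally_reference()]
#' @export
events_from_counts <- function(counts) {
  stopifnot(all(c("station_label", "n_events", "n_gtv_affected") %in% names(counts)))
  rows <- lapply(seq_len(nrow(counts)), function(r) {
    k <- counts$n_events[r]
    if (is.na(k) || k == 0) return(NULL)
    kg <- counts$n_gtv_affected[r]
    m <- if ("mean_actual_over_idea" %in% names(counts)) {
      counts$mean_actual_over_idea[r]
    } else NA_real_
    data.frame(
      patient_id = sprintf("%s_e%02d", counts$station_label[r], seq_len(k)),
      station_label = counts$station_label[r],
      gtv_affected = rep(c(1L, 0L), c(kg, k - kg)),
      actual_over_idea = rep(m, k),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out) || !is.data.frame(out)) out <- classify_empty_events()
  class(out) <- c("recurrence_events", "data.frame")
  out
}

#' Reference station-level recurrence tally
#'
#' The published per-station recurrence statistics of a 180-patient SCLC
#' radiotherapy cohort (94 relapsing patients, 170 station-level events),
#' shipped as a plain-text reference table for aggregate re-analysis:
#' event counts, mean and range of the covered proportion of the ideal
#' station area, and the GTV-affected / CTV-minus-GTV split. Stations 2L
#' and 3P had no events; their proportions are `NA`.
#'
#' @return data frame with one row per station in [station_labels()] order.
#' @export
recurrence_tally_reference <- function() {
  path <- system.file("extdata", "station_recurrence_reference.csv",
                      package = "ctvrecur", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE,
           colClasses = c(station_label = "character"))
}

#' Aggregate recurrence events into a per-station tally
#'
#' Per-station event counts, the GTV-affected / CTV-minus-GTV split, and
#' mean and range of the covered ideal-area proportion. Stations with no
#' events are reported with `n_events = 0` and `NA` proportions. The output
#' is permutation-invariant in the event list.
#'
#' @param events a `recurrence_events` data frame (e.g. from
#'   [classify_cohort_recurrences()] or [events_from_counts()]).
#' @return An object of class `station_tally`: list with `by_station`
#'   (16-row data frame in station order) and `total` (grand event count).
#' @export
tally_by_station <- function(events) {
  labs <- station_labels()
  if (nrow(events) > 0 && !all(events$station_label %in% labs)) {
    ctv_stop("ctv_station_error", "unknown station label(s) in events: %s",
             paste(setdiff(unique(events$station_label), labs), collapse = ", "))
  }
  by_station <- do.call(rbind, lapply(labs, function(lab) {
    e <- events[events$station_label == lab, , drop = FALSE]
    k <- nrow(e)
    prop <- e$actual_over_idea[!is.na(e$actual_over_idea)]
    data.frame(
      station_label = lab,
      n_events = k,
      mean_actual_over_idea = if (length(prop)) mean(prop) else NA_real_,
      min_actual_over_idea = if (length(prop)) min(prop) else NA_real_,
      max_actual_over_idea = if (length(prop)) max(prop) else NA_real_,
      n_gtv_affected = sum(e$gtv_affected == 1L),
      n_ctv_minus_gtv = sum(e$gtv_affected == 0L),
      stringsAsFactors = FALSE)
  }))
  rownames(by_station) <- NULL
  structure(list(by_station = by_station, total = nrow(events)),
            class = "station_tally")
}

#' @export
print.station_tally <- function(x, ...) {
  df <- x$by_station
  df$mean_actual_over_idea <- ifelse(
    is.na(df$mean_actual_over_idea), "-",
    sprintf("%.3f", df$mean_actual_over_idea))
  print(df, row.names = FALSE)
  cat(sprintf("Total events: %d\n", x$total))
  invisible(x)
}

#' Share of events falling in a set of stations
#'
#' @param tally a `station_tally` from [tally_by_station()].
#' @param stations character vector of station labels.
#' @return fraction of all events in the named stations, in `[0, 1]`.
#' @export
#' @examples
#' tal <- tally_by_station(events_from_counts(recurrence_tally_reference()))
#' top_station_share(tal, c("10R", "10L", "4R", "7")) # 115/170
top_station_share <- function(tally, stations) {
  stopifnot(inherits(tally, "station_tally"))
  ln_index(stations) # validates labels
  if (tally$total == 0) {
    ctv_stop("ctv_tally_error", "no events: share is undefined")
  }
  sum(tally$by_station$n_events[tally$by_station$station_label %in% stations]) /
    tally$total
}

#' Recurrence rate by initially involved station
#'
#' For each station, the fraction of patients whose initial gross disease
#' involved the station (any gross-disease overlap, i.e. `RgtvLN > 0` in
#' the extracted features) that later relapsed. Stations no patient
#' involved get an `NA` rate.
#'
#' @param features cohort feature data frame (from
#'   [extract_cohort_features()] or [simulate_feature_cohort()]) containing
#'   the `RgtvLN1..16` columns and a `relapse` column (or pass `relapse`
#'   separately).
#' @param relapse optional 0/1 vector overriding `features$relapse`.
#' @return data frame with columns `station_label`, `n_involved`,
#'   `n_relapsed`, `rate`.
#' @export
initial_region_recurrence_rates <- function(features, relapse = NULL) {
  if (is.null(relapse)) relapse <- features$relapse
  stopifnot(!is.null(relapse), length(relapse) == nrow(features))
  labs <- station_labels()
  out <- do.call(rbind, lapply(1:16, function(i) {
    inv <- features[[paste0("RgtvLN", i)]] > 0
    n_inv <- sum(inv)
    n_rel <- sum(inv & relapse == 1)
    data.frame(station_label = labs[i], n_involved = n_inv,
               n_relapsed = n_rel,
               rate = if (n_inv > 0) n_rel / n_inv else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
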