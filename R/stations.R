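#' Lymph-node station index/label correspondence
#'
#' The sixteen mediastinal and hilar station labels of the IASLC map used
#' throughout the package, in the fixed index order LN1..LN16:
#' 1R, 1L, 2R, 2L, 3A, 3P, 4R, 4L, 5, 6, 7, 8, 10R, 10L, 11R, 11L.
#' All per-station vectors (masks, ratios, tallies) follow this order.
#'
#' @return `station_labels()` returns the 16 labels in index order;
#'   `station_map()` returns a data frame with `ln_index` and
#'   `station_label` columns.
#' @export
#' @examples
#' station_labels()[13] # "10R"
#' ln_index("4R")       # 7
station_labels <- function() {
  c("1R", "1L", "2R", "2L", "3A", "3P", "4R", "4L",
    "5", "6", "7", "8", "10R", "10L", "11R", "11L")
}

#' @rdname station_labels
#' @export
station_map <- function() {
  data.frame(ln_index = 1:16, station_label = station_labels(),
             stringsAsFactors = FALSE)
}

#' @rdname station_labels
#' @param label one or more station labels.
#' @export
ln_index <- function(label) {
  idx <- match(as.character(label), station_labels())
  if (anyNA(idx)) {
    ctv_stop("ctv_station_error", "unknown station label(s): %s",
             paste(unique(label[is.na(idx)]), collapse = ", "))
  }
  idx
}

# stations whose CTV overlap is reported as an explicit binary flag,
# in feature order
overlap_flag_stations <- function() c("4L", "4R", "5", "6", "7", "11L", "11R")
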