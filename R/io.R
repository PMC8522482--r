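## CSV contracts. Months serialise as "YYYY-MM", dates as ISO-8601, UTF-8,
## comma-delimited with a header row.

area_cols <- function() {
  readr::cols(
    area_id = readr::col_character(), lat = readr::col_double(),
    lon = readr::col_double(), imd_score = readr::col_double(),
    total_pop = readr::col_integer(), ethnic_density = readr::col_double(),
    pop_density = readr::col_double(), urban_flag = readr::col_logical()
  )
}

event_cols <- function() {
  readr::cols(
    event_id = readr::col_character(), lat = readr::col_double(),
    lon = readr::col_double(), launch_date = readr::col_date(),
    closure_date = readr::col_date()
  )
}

finisher_cols <- function() {
  readr::cols(area_id = readr::col_character(), month = readr::col_character(),
              count = readr::col_integer())
}

#' Read and write the pipeline's CSV tables
#'
#' Readers enforce the column types of the three input contracts (small-area
#' attributes, event registry, long-format monthly finisher counts) and of
#' the distance panel; writers emit plain UTF-8 CSV that round-trips through
#' the readers.
#'
#' @param path file path.
#' @return a tibble in the corresponding schema.
#' @export
read_areas_csv <- function(path) {
  readr::read_csv(path, col_types = area_cols(), progress = FALSE)
}

#' @rdname read_areas_csv
#' @export
read_events_csv <- function(path) {
  readr::read_csv(path, col_types = event_cols(), progress = FALSE)
}

#' @rdname read_areas_csv
#' @export
read_finishers_csv <- function(path) {
  readr::read_csv(path, col_types = finisher_cols(), progress = FALSE)
}

#' @rdname read_areas_csv
#' @export
read_distance_panel_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    area_id = readr::col_character(), month = readr::col_character(),
    distance_km = readr::col_double(), nearest_event_id = readr::col_character()
  ), progress = FALSE)
}

#' @rdname read_areas_csv
#' @param x tibble to serialise.
#' @export
write_table_csv <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}
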