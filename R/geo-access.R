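## Distance-to-nearest-event panel construction.

#' Geodesic distance in kilometres
#'
#' Distance between WGS84 points, vectorised with recycling. The default is
#' the ellipsoidal geodesic (Karney's algorithm via [geosphere::distGeo()]),
#' i.e. the "direct linear" distance; `method = "haversine"` gives the
#' great-circle distance on a sphere of radius 6371.0088 km as a cross-check
#' variant.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees.
#' @param method `"wgs84"` (default) or `"haversine"`.
#' @return nonnegative distances in km.
#' @examples
#' geodesic_km(0, 0, 0, 1)  # one degree of longitude at the equator
#' @export
geodesic_km <- function(lat1, lon1, lat2, lon2, method = c("wgs84", "haversine")) {
  method <- match.arg(method)
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  p1 <- cbind(lon1, lat1)
  p2 <- cbind(lon2, lat2)
  m <- switch(method,
    wgs84 = geosphere::distGeo(p1, p2),
    haversine = geosphere::distHaversine(p1, p2, r = 6371008.8)
  )
  m / 1000
}

check_coords <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(lat < -90 | lat > 90)) {
    stop("latitude outside [-90, 90]", call. = FALSE)
  }
  if (any(!is.finite(lon)) || any(lon < -180 | lon > 180)) {
    stop("longitude outside [-180, 180]", call. = FALSE)
  }
  invisible(NULL)
}

#' Events active on a date
#'
#' An event is active on `date` iff it has launched on or before `date` and
#' has not yet closed: launch dates are inclusive, closure dates exclusive
#' (an event closing on the query date no longer counts).
#'
#' @param registry event tibble with `event_id`, `lat`, `lon`,
#'   `launch_date`, `closure_date` (`NA` = still open).
#' @param date a `Date`.
#' @return the active subset of `registry`.
#' @export
active_events <- function(registry, date) {
  stopifnot(inherits(date, "Date"), length(date) == 1L)
  check_registry(registry)
  dplyr::filter(registry,
                .data$launch_date <= date,
                is.na(.data$closure_date) | .data$closure_date > date)
}

check_registry <- function(registry) {
  req <- c("event_id", "lat", "lon", "launch_date", "closure_date")
  miss <- setdiff(req, names(registry))
  if (length(miss) > 0) {
    stop("registry lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- !is.na(registry$closure_date) & registry$closure_date <= registry$launch_date
  if (any(bad)) {
    stop("closure_date must be strictly after launch_date (event ",
         registry$event_id[which(bad)[1]], ")", call. = FALSE)
  }
  invisible(NULL)
}

#' Build the per-area monthly distance panel
#'
#' For every area and every month of `month_range`, the geodesic distance
#' (km) from the area centroid to the nearest event in operation on the 15th
#' of that month, together with that event's id. Ties in distance are broken
#' lexicographically by `event_id` for reproducibility. Distances are
#' carried at full precision; round only at report time.
#'
#' @param areas tibble with `area_id`, `lat`, `lon` (plus anything else).
#' @param registry event tibble as in [active_events()].
#' @param month_range character vector of `"YYYY-MM"` months.
#' @param method distance method passed to [geodesic_km()].
#' @return tibble `area_id`, `month`, `distance_km`, `nearest_event_id`,
#'   one row per (area, month), ordered by month then area.
#' @export
build_distance_panel <- function(areas, registry, month_range,
                                 method = c("wgs84", "haversine")) {
  method <- match.arg(method)
  check_registry(registry)
  stopifnot(nrow(areas) > 0, length(month_range) > 0)
  months <- check_month(month_range)
  registry <- dplyr::arrange(registry, .data$event_id)

  ## area x event distance matrix, computed once; monthly panels are argmins
  ## over the columns active that month.
  dist_mat <- vapply(seq_len(nrow(registry)), function(j) {
    geodesic_km(areas$lat, areas$lon, registry$lat[j], registry$lon[j],
                method = method)
  }, numeric(nrow(areas)))
  dist_mat <- matrix(dist_mat, nrow = nrow(areas))

  per_month <- purrr::map(months, function(m) {
    date15 <- month_mid_day(m)
    active <- which(registry$launch_date <= date15 &
                      (is.na(registry$closure_date) | registry$closure_date > date15))
    if (length(active) == 0L) {
      stop("no event active on the 15th of ", m, call. = FALSE)
    }
    sub <- dist_mat[, active, drop = FALSE]
    j <- max.col(-sub, ties.method = "first")
    tibble::tibble(
      area_id = areas$area_id,
      month = m,
      distance_km = sub[cbind(seq_len(nrow(sub)), j)],
      nearest_event_id = registry$event_id[active][j]
    )
  })
  dplyr::bind_rows(per_month)
}
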