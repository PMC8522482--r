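## Deprivation-quintile descriptives: quintile assignment, per-period
## quintile means of distance and participation rate, and the summary table
## of time-invariant area characteristics.

#' Assign deprivation quintiles
#'
#' Areas ranked by deprivation score ascending are split into 5 groups as
#' equal as possible, any remainder going to the lower (less deprived)
#' quintiles. Quintile 1 is least deprived, quintile 5 most deprived. Score
#' ties are broken by `area_id` so the assignment is deterministic.
#'
#' @param areas area tibble (`area_id`, `imd_score`); at least 5 areas.
#' @return tibble `area_id`, `quintile` (integer 1--5).
#' @export
assign_quintiles <- function(areas) {
  n <- nrow(areas)
  if (n < 5) stop("need at least 5 areas to form quintiles", call. = FALSE)
  ord <- order(areas$imd_score, areas$area_id)
  base <- n %/% 5L
  sizes <- base + as.integer(seq_len(5L) <= n %% 5L)
  quintile <- rep(1:5, times = sizes)
  tibble::tibble(area_id = areas$area_id[ord], quintile = quintile) |>
    dplyr::arrange(.data$area_id)
}

#' Quintile series of distance and participation rate
#'
#' Per period (month or year) and deprivation quintile: the unweighted mean
#' over member areas of the distance to the nearest event, and the
#' unweighted mean of the area-level participation rate (1000 x count /
#' population). Yearly rates use the year's summed counts and the
#' within-year mean distance. An `overall` row repeats the statistics over
#' all areas. `pooled = TRUE` switches the rate to pooled counts over pooled
#' population (a population-weighted variant, off by default since the
#' analysis is unweighted by design).
#'
#' @param areas area tibble.
#' @param distance_panel tibble from [build_distance_panel()].
#' @param finisher_panel tibble `area_id`, `month`, `count`.
#' @param by `"month"` or `"year"`.
#' @param pooled use pooled-rate variant?
#' @return tibble of class `quintile_summary`: `period`, `quintile`
#'   (`"1"`..`"5"`, `"overall"`), `mean_distance_km`, `finishers_per_1000`,
#'   `n_areas`.
#' @export
quintile_series <- function(areas, distance_panel, finisher_panel,
                            by = c("month", "year"), pooled = FALSE) {
  by <- match.arg(by)
  q <- assign_quintiles(areas)
  cells <- distance_panel |>
    dplyr::inner_join(finisher_panel, by = c("area_id", "month")) |>
    dplyr::inner_join(dplyr::select(areas, "area_id", "total_pop"), by = "area_id") |>
    dplyr::inner_join(q, by = "area_id")
  if (nrow(cells) < nrow(distance_panel)) {
    stop("finisher panel does not cover every (area, month) of the distance panel",
         call. = FALSE)
  }
  cells$period <- if (by == "month") cells$month else
    as.character(month_year(cells$month))

  ## collapse to one record per (area, period): yearly count = summed months,
  ## yearly distance = within-year mean.
  per_area <- cells |>
    dplyr::summarise(
      count = sum(.data$count),
      distance_km = mean(.data$distance_km),
      total_pop = .data$total_pop[1],
      quintile = .data$quintile[1],
      .by = c("area_id", "period")
    )

  summarise_group <- function(df) {
    if (pooled) {
      rate <- 1000 * sum(df$count) / sum(df$total_pop)
    } else {
      rate <- mean(1000 * df$count / df$total_pop)
    }
    tibble::tibble(mean_distance_km = mean(df$distance_km),
                   finishers_per_1000 = rate,
                   n_areas = dplyr::n_distinct(df$area_id))
  }

  by_q <- per_area |>
    dplyr::group_by(.data$period, quintile = as.character(.data$quintile)) |>
    dplyr::group_modify(~summarise_group(.x)) |>
    dplyr::ungroup()
  overall <- per_area |>
    dplyr::group_by(.data$period) |>
    dplyr::group_modify(~summarise_group(.x)) |>
    dplyr::ungroup() |>
    dplyr::mutate(quintile = "overall", .after = "period")
  out <- dplyr::bind_rows(by_q, overall) |>
    dplyr::arrange(.data$period, .data$quintile)
  class(out) <- c("quintile_summary", class(out))
  out
}

#' Summary of time-invariant area characteristics
#'
#' Mean, minimum, quartiles, median and maximum of each area-level covariate
#' (deprivation score, ethnic density, population, population density).
#' Quartiles use linear interpolation (quantile type 7).
#'
#' @param areas area tibble.
#' @return tibble `variable`, `mean`, `min`, `p25`, `median`, `p75`, `max`.
#' @export
panel_summary <- function(areas) {
  stopifnot(nrow(areas) > 0)
  vars <- c("imd_score", "ethnic_density", "total_pop", "pop_density")
  vars <- intersect(vars, names(areas))
  purrr::map_dfr(vars, function(v) {
    x <- areas[[v]]
    qs <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    tibble::tibble(variable = v, mean = mean(x), min = min(x),
                   p25 = qs[1], median = qs[2], p75 = qs[3], max = max(x))
  })
}

#' Plot a quintile series
#'
#' One line per deprivation quintile (overall dashed in black) against
#' time, for either the mean distance or the participation rate.
#'
#' @param object a `quintile_summary` built with `by = "month"`.
#' @param outcome `"distance"` or `"participation"`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.quintile_summary <- function(object, outcome = c("distance", "participation"),
                                      ...) {
  outcome <- match.arg(outcome)
  ycol <- if (outcome == "distance") "mean_distance_km" else "finishers_per_1000"
  ylab <- if (outcome == "distance") "Mean distance to nearest event (km)" else
    "Monthly finishers per 1000 persons"
  df <- dplyr::mutate(object, date = month_mid_day(.data$period))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$date, y = .data[[ycol]],
                                   colour = .data$quintile,
                                   linetype = .data$quintile == "overall")) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(values = c(`FALSE` = "solid", `TRUE` = "dashed"),
                                   guide = "none") +
    ggplot2::labs(x = NULL, y = ylab, colour = "IMD quintile") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.quintile_summary
#' @export
plot_quintile_series <- function(object, outcome = c("distance", "participation"),
                                 ...) {
  autoplot.quintile_summary(object, outcome = outcome, ...)
}
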