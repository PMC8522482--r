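## Yearly multivariable determinants of participation: offset-Poisson models
## of yearly finisher counts on deprivation, ethnic density, (scaled)
## population density and distance to the nearest event, one model per year,
## with quasi-Poisson and urban/rural sensitivity variants.

#' Scale divisor applied to population density before fitting
#'
#' Population density enters the determinant models in thousands of persons
#' per km2, keeping its coefficient on a magnitude comparable with the other
#' covariates.
#' @export
pop_density_scale <- 1000

#' Yearly determinants of participation
#'
#' For each requested year: finisher counts are summed over the year's
#' months per area, the distance covariate is the mean of the area's monthly
#' distances within that year, and a log-link Poisson model of the yearly
#' count on deprivation score, ethnic density, population density (in
#' thousands of persons/km2) and distance (km) is fitted with log total
#' population as the offset. `family = "quasipoisson"` keeps the Poisson
#' point estimates and rescales standard errors by the square root of the
#' Pearson dispersion. `stratum` restricts to urban or rural areas.
#'
#' Deprivation scores (and the other area covariates) are treated as
#' time-invariant.
#'
#' @param areas area tibble (`area_id`, `imd_score`, `ethnic_density`,
#'   `pop_density`, `total_pop`, `urban_flag`).
#' @param finisher_panel tibble `area_id`, `month`, `count`.
#' @param distance_panel tibble from [build_distance_panel()].
#' @param years integer years to fit; default, all years fully covered by
#'   both panels.
#' @param family `"poisson"` or `"quasipoisson"`.
#' @param stratum `"all"`, `"urban"` or `"rural"`.
#' @return tibble of class `coefficient_table`: one row per (year, term)
#'   with `estimate`, `std_error`, `log_likelihood`, `aic`, `n_obs`,
#'   `dispersion`, `family`, `stratum`. Terms: `intercept`, `imd_score`,
#'   `ethnic_density`, `pop_density_scaled`, `distance_km`. Years that are
#'   non-estimable (zero finishers in the stratum) are omitted with a
#'   message.
#' @export
fit_yearly_determinants <- function(areas, finisher_panel, distance_panel,
                                    years = NULL,
                                    family = c("poisson", "quasipoisson"),
                                    stratum = c("all", "urban", "rural")) {
  family <- match.arg(family)
  stratum <- match.arg(stratum)

  f_months <- unique(finisher_panel$month)
  d_months <- unique(distance_panel$month)
  if (is.null(years)) {
    years <- intersect(full_years(f_months), full_years(d_months))
    if (length(years) == 0) stop("no year fully covered by both panels", call. = FALSE)
  }
  years <- sort(as.integer(years))
  for (yr in years) {
    need <- month_seq(sprintf("%d-01", yr), sprintf("%d-12", yr))
    missing <- setdiff(need, intersect(f_months, d_months))
    if (length(missing) > 0) {
      stop("panels do not cover all months of ", yr, " (missing ",
           paste(head(missing, 3), collapse = ", "), ")", call. = FALSE)
    }
  }

  area_set <- switch(stratum,
    all = areas,
    urban = dplyr::filter(areas, .data$urban_flag),
    rural = dplyr::filter(areas, !.data$urban_flag)
  )
  if (nrow(area_set) == 0) stop("stratum '", stratum, "' contains no areas", call. = FALSE)
  zero_pop <- area_set$total_pop <= 0
  if (any(zero_pop)) {
    rlang::inform(paste0("fit_yearly_determinants: excluding ", sum(zero_pop),
                         " area(s) with zero population"))
    area_set <- area_set[!zero_pop, , drop = FALSE]
  }

  rows <- purrr::map(years, function(yr) {
    yearly <- yearly_covariates(area_set, finisher_panel, distance_panel, yr)
    if (sum(yearly$count) == 0) {
      rlang::inform(paste0("fit_yearly_determinants: ", yr, " (", stratum,
                           ") has zero finishers; year omitted as non-estimable"))
      return(NULL)
    }
    X <- cbind(intercept = 1,
               imd_score = yearly$imd_score,
               ethnic_density = yearly$ethnic_density,
               pop_density_scaled = yearly$pop_density / pop_density_scale,
               distance_km = yearly$distance_km)
    fit <- fit_poisson_glm(X, yearly$count, offset = log(yearly$total_pop))
    se <- fit$standard_errors
    if (family == "quasipoisson") se <- se * sqrt(fit$dispersion)
    tibble::tibble(
      year = yr,
      term = names(fit$coefficients),
      estimate = as.numeric(fit$coefficients),
      std_error = as.numeric(se),
      log_likelihood = fit$log_likelihood,
      aic = fit$aic,
      n_obs = fit$nobs,
      dispersion = fit$dispersion,
      family = family,
      stratum = stratum
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("coefficient_table", class(out))
  out
}

## Years for which every calendar month is present.
full_years <- function(months) {
  tab <- table(month_year(months))
  as.integer(names(tab)[tab == 12L])
}

yearly_covariates <- function(area_set, finisher_panel, distance_panel, yr) {
  counts <- finisher_panel |>
    dplyr::filter(month_year(.data$month) == yr) |>
    dplyr::summarise(count = sum(.data$count), .by = "area_id")
  dists <- distance_panel |>
    dplyr::filter(month_year(.data$month) == yr) |>
    dplyr::summarise(distance_km = mean(.data$distance_km), .by = "area_id")
  area_set |>
    dplyr::inner_join(counts, by = "area_id") |>
    dplyr::inner_join(dists, by = "area_id")
}

#' Plot a coefficient table
#'
#' Yearly estimates with ±2 SE ribbons, one facet per model term
#' (intercept omitted by default).
#'
#' @param object a `coefficient_table`.
#' @param include_intercept include the intercept facet?
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.coefficient_table <- function(object, include_intercept = FALSE, ...) {
  df <- object
  if (!include_intercept) df <- dplyr::filter(df, .data$term != "intercept")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$estimate - 2 * .data$std_error,
                                      ymax = .data$estimate + 2 * .data$std_error),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "Year", y = "Coefficient (log rate scale)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.coefficient_table
#' @export
plot_determinants <- function(object, include_intercept = FALSE, ...) {
  autoplot.coefficient_table(object, include_intercept = include_intercept, ...)
}
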