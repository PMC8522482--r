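## Synthetic geography, event roll-out and finisher counts.
##
## The generator is the package's stand-in for the real English small-area
## data: it reproduces the statistical structure the downstream analysis
## assumes (right-skewed deprivation, urban clustering, density-correlated
## ethnic density, a two-phase event roll-out sited preferentially in dense
## places, and log-link Poisson counts with a population offset) without any
## claim to geographic realism.

## Deprivation marginal: Beta(1.1, 3.969) rescaled to (0, 100]. Mean 21.7 by
## construction; the shape-1.1 right skew puts the median near 17.4,
## matching the shape of the national score distribution.
IMD_SHAPE1 <- 1.1
IMD_MEAN <- 21.7
IMD_SHAPE2 <- IMD_SHAPE1 * (100 - IMD_MEAN) / IMD_MEAN

#' Moments of the synthetic deprivation-score marginal
#'
#' The deprivation score is drawn as `100 * Beta(shape1, shape2)` with
#' shapes fixed so the mean is 21.7 and the distribution is right-skewed
#' (median near 17.4). Exposed so tests can check sample moments against the
#' analytic values.
#'
#' @return list with `shape1`, `shape2`, `mean` and `sd` (score scale).
#' @export
imd_marginal_moments <- function() {
  a <- IMD_SHAPE1
  b <- IMD_SHAPE2
  list(shape1 = a, shape2 = b,
       mean = 100 * a / (a + b),
       sd = 100 * sqrt(a * b / ((a + b)^2 * (a + b + 1))))
}

#' Generate a synthetic small-area geography
#'
#' Draws `n_areas` areas with centroids inside the configured bounding box:
#' urban areas cluster around `n_cities` random city centres, rural areas
#' scatter uniformly. Deprivation scores follow the right-skewed marginal of
#' [imd_marginal_moments()] and are rank-coupled to an urbanicity latent so
#' that, as in English data, deprivation concentrates in dense urban areas.
#' Ethnic density increases with population density and urbanicity.
#'
#' @param config a [synth_config()].
#' @return tibble with one row per area: `area_id`, `lat`, `lon`,
#'   `imd_score` (0 least -- 100 most deprived), `total_pop`,
#'   `ethnic_density` (percent), `pop_density` (persons/km2), `urban_flag`.
#' @export
generate_areas <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_areas
  bb <- config$bbox
  with_seed(config$seed, {
    margin_lon <- 0.1 * (bb[["lon_max"]] - bb[["lon_min"]])
    margin_lat <- 0.1 * (bb[["lat_max"]] - bb[["lat_min"]])
    cities <- tibble::tibble(
      lon = runif(config$n_cities, bb[["lon_min"]] + margin_lon, bb[["lon_max"]] - margin_lon),
      lat = runif(config$n_cities, bb[["lat_min"]] + margin_lat, bb[["lat_max"]] - margin_lat)
    )

    urban <- rbinom(n, 1L, config$urban_fraction) == 1L
    city_of <- sample.int(config$n_cities, n, replace = TRUE)
    lon <- ifelse(urban,
                  cities$lon[city_of] + rnorm(n, 0, 0.08),
                  runif(n, bb[["lon_min"]], bb[["lon_max"]]))
    lat <- ifelse(urban,
                  cities$lat[city_of] + rnorm(n, 0, 0.08),
                  runif(n, bb[["lat_min"]], bb[["lat_max"]]))
    lon <- pmin(pmax(lon, bb[["lon_min"]]), bb[["lon_max"]])
    lat <- pmin(pmax(lat, bb[["lat_min"]]), bb[["lat_max"]])

    pop_density <- ifelse(urban,
                          rlnorm(n, log(4500), 0.7),
                          rlnorm(n, log(250), 0.6))

    ## Deprivation: exact Beta marginal, rank-coupled to urbanicity so the
    ## marginal moments are analytic while deprivation still tracks cities.
    imd_draws <- 100 * rbeta(n, IMD_SHAPE1, IMD_SHAPE2)
    ## Coupling strengths are deliberately moderate: strong enough for the
    ## urban-deprivation gradient the analysis expects, weak enough that the
    ## linear distance model keeps positive predictions at both deprivation
    ## extremes (as in the real data, where the distance RII peaks near 3.5).
    ## Density enters through its within-stratum residual so the coupling
    ## does not inflate the urban-rural deprivation gap beyond `0.35 * urban`.
    z_dens <- as.numeric(scale(log(pop_density)))
    log_dens <- log(pop_density)
    z_within <- (log_dens - ifelse(urban, mean(log_dens[urban]), mean(log_dens[!urban]))) /
      sd(log_dens - ifelse(urban, mean(log_dens[urban]), mean(log_dens[!urban])))
    urban_latent <- 0.35 * urban + 0.25 * z_within + rnorm(n)
    imd_score <- sort(imd_draws)[rank(urban_latent, ties.method = "first")]

    eth_latent <- -2.6 + 1.1 * z_dens + 0.015 * (imd_score - IMD_MEAN) + rnorm(n, 0, 0.8)
    ethnic_density <- 100 * plogis(eth_latent)

    total_pop <- as.integer(pmin(pmax(round(rlnorm(n, log(1600), 0.12)), 934), 7976))

    tibble::tibble(
      area_id = sprintf("A%05d", seq_len(n)),
      lat = lat, lon = lon,
      imd_score = imd_score,
      total_pop = total_pop,
      ethnic_density = ethnic_density,
      pop_density = pop_density,
      urban_flag = urban
    )
  })
}

#' Generate a synthetic event registry
#'
#' Launches events following the cumulative yearly schedule in the config.
#' The first-year stock launches on the first day of the study span (it
#' represents events already operating when the window opens, and
#' guarantees at least one active event in every month); in later years,
#' launch dates fall on days 1--15 of a month of that year, so every event
#' of a year is active by the 15th of its December. Sites are drawn at area centroids (with small
#' jitter) with probability proportional to `pop_density^b`, where the
#' exponent ramps linearly from 0 in the first year to `siting_bias` in the
#' last: the roll-out starts geographically unbiased and becomes
#' increasingly concentrated near dense (hence more deprived) areas, which
#' is what drives the emerging deprivation gradient in distance.
#'
#' @param config a [synth_config()].
#' @param areas tibble from [generate_areas()].
#' @return tibble: `event_id`, `lat`, `lon`, `launch_date`, `closure_date`
#'   (`NA` throughout; the generator never closes events).
#' @export
generate_event_registry <- function(config, areas) {
  stopifnot(inherits(config, "synth_config"), nrow(areas) > 0)
  schedule <- config$n_events_by_year
  n_new <- diff(c(0L, schedule))
  n_years <- length(config$years)
  bb <- config$bbox
  with_seed(config$seed + 1L, {
    rows <- purrr::map2(seq_along(config$years), n_new, function(yi, k) {
      if (k == 0L) return(NULL)
      yr <- config$years[yi]
      frac <- if (n_years == 1L) 1 else (yi - 1) / (n_years - 1)
      w <- areas$pop_density^config$siting_bias
      months_yr <- config$months[month_year(config$months) == yr]
      ## ramp: each event is either sited uniformly over the territory
      ## (early roll-out) or at a density-weighted area centroid (late).
      near_area <- runif(k) < frac
      idx <- sample.int(nrow(areas), k, replace = TRUE, prob = w)
      lat <- ifelse(near_area,
                    areas$lat[idx] + rnorm(k, 0, 0.02),
                    runif(k, bb[["lat_min"]], bb[["lat_max"]]))
      lon <- ifelse(near_area,
                    areas$lon[idx] + rnorm(k, 0, 0.02),
                    runif(k, bb[["lon_min"]], bb[["lon_max"]]))
      if (yi == 1L) {
        ## the first-year stock predates the study window: active throughout
        launch_date <- rep(month_first_day(config$months[1]), k)
      } else {
        launch_month <- months_yr[sample.int(length(months_yr), k, replace = TRUE)]
        launch_day <- sample.int(15L, k, replace = TRUE)
        launch_date <- as.Date(sprintf("%s-%02d", launch_month, launch_day))
      }
      tibble::tibble(lat = lat, lon = lon, launch_date = launch_date)
    })
    events <- dplyr::bind_rows(rows)
    events <- dplyr::arrange(events, .data$launch_date)
    tibble::tibble(
      event_id = sprintf("E%04d", seq_len(nrow(events))),
      lat = events$lat, lon = events$lon,
      launch_date = events$launch_date,
      closure_date = as.Date(rep(NA, nrow(events)))
    )
  })
}

#' Simulate monthly finisher counts
#'
#' Draws one count per (area, month) cell of the distance panel from the
#' generative model described in [generative_truth()]: a log-link Poisson
#' rate per person-month built from the area covariates and that month's
#' distance to the nearest event, scaled by total population (the offset)
#' and the seasonal factor. When `truth$dispersion > 1` counts are
#' gamma-mixed Poisson (negative binomial parameterised so every cell has
#' variance/mean equal to `dispersion`).
#'
#' @param areas tibble from [generate_areas()] (or the same schema).
#' @param distance_panel tibble from [build_distance_panel()].
#' @param truth a [generative_truth()].
#' @param seed integer seed.
#' @return tibble `area_id`, `month`, `count` covering exactly the panel's
#'   cells.
#' @export
simulate_finisher_counts <- function(areas, distance_panel, truth, seed) {
  stopifnot(inherits(truth, "generative_truth"))
  months <- sort(unique(distance_panel$month))
  grid <- tidyr::expand_grid(area_id = areas$area_id, month = months)
  cells <- dplyr::left_join(grid, distance_panel, by = c("area_id", "month"))
  missing <- dplyr::filter(cells, is.na(.data$distance_km))
  if (nrow(missing) > 0) {
    stop("distance panel is missing cell (", missing$area_id[1], ", ",
         missing$month[1], ")", call. = FALSE)
  }
  cells <- dplyr::left_join(cells, areas, by = "area_id")
  mu <- expected_finisher_count(cells, truth)
  with_seed(seed, {
    count <- if (truth$dispersion > 1) {
      rnbinom(length(mu), mu = mu, size = mu / (truth$dispersion - 1))
    } else {
      rpois(length(mu), mu)
    }
    tibble::tibble(area_id = cells$area_id, month = cells$month,
                   count = as.integer(count))
  })
}

#' @rdname simulate_finisher_counts
#' @param cells tibble holding `total_pop`, `imd_score`, `ethnic_density`,
#'   `pop_density`, `distance_km` and `month` columns.
#' @return `expected_finisher_count()`: the closed-form Poisson mean of each
#'   cell (no sampling).
#' @export
expected_finisher_count <- function(cells, truth) {
  log_rate <- truth$alpha +
    truth$beta_imd * cells$imd_score +
    truth$beta_eth * cells$ethnic_density +
    truth$beta_dens * cells$pop_density / 1000 +
    truth$beta_dist * cells$distance_km
  cells$total_pop * exp(log_rate) *
    seasonal_factor(cells$month, truth$seasonal_amplitude)
}

#' Generate a complete synthetic study dataset
#'
#' Convenience wrapper running the three generators plus the distance panel:
#' the full input set the analysis pipeline consumes.
#'
#' @param config a [synth_config()].
#' @return list of class `synth_dataset` with `areas`, `events`,
#'   `distance_panel`, `finishers` and the `config`.
#' @export
simulate_dataset <- function(config) {
  areas <- generate_areas(config)
  events <- generate_event_registry(config, areas)
  panel <- build_distance_panel(areas, events, config$months)
  finishers <- simulate_finisher_counts(areas, panel, config$truth,
                                        seed = config$seed + 2L)
  structure(list(areas = areas, events = events, distance_panel = panel,
                 finishers = finishers, config = config),
            class = "synth_dataset")
}
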