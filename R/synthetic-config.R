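#' Ground-truth parameters for the synthetic participation process
#'
#' The generative model for finisher counts is a log-link Poisson (optionally
#' gamma-mixed for overdispersion) on the area covariates the analysis later
#' tries to recover:
#' \deqn{count_{am} \sim Poisson(pop_a \cdot e^{\alpha + \beta_{imd} imd_a +
#'   \beta_{eth} eth_a + \beta_{dens} dens_a/1000 + \beta_{dist} dist_{am}}
#'   \cdot s(m))}
#' where \eqn{s(m)} is a month-of-year seasonal factor with mean 1 over a
#' calendar year.
#'
#' Defaults mirror the magnitudes reported for English small-area data in the
#' late study period: roughly a 3.5% drop in the participation rate per unit
#' of deprivation score, 0.9% per percentage point of ethnic density, 0.8%
#' per thousand persons/km2 of population density and 9% per km of distance
#' to the nearest event.
#'
#' @param alpha baseline log rate per person-month.
#' @param beta_imd log-rate effect per unit deprivation score (0--100 scale).
#' @param beta_eth log-rate effect per percentage point ethnic density.
#' @param beta_dens log-rate effect per thousand persons/km2.
#' @param beta_dist log-rate effect per km distance to nearest event.
#' @param seasonal_amplitude amplitude in `[0, 1)` of the sinusoidal
#'   month-of-year modulation (peak in July); 0 switches seasonality off.
#' @param dispersion variance/mean ratio of counts; 1 = pure Poisson, values
#'   above 1 use a gamma-mixed Poisson (negative binomial) with exactly this
#'   variance/mean ratio in every cell.
#' @return an object of class `generative_truth`.
#' @export
generative_truth <- function(alpha = -4.4,
                             beta_imd = -0.035,
                             beta_eth = -0.009,
                             beta_dens = -0.008,
                             beta_dist = -0.09,
                             seasonal_amplitude = 0.25,
                             dispersion = 1) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (!is.numeric(dispersion) || dispersion < 1) {
    stop("`dispersion` must be >= 1 (1 = pure Poisson)", call. = FALSE)
  }
  if (seasonal_amplitude < 0 || seasonal_amplitude >= 1) {
    stop("`seasonal_amplitude` must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(alpha = alpha, beta_imd = beta_imd, beta_eth = beta_eth,
         beta_dens = beta_dens, beta_dist = beta_dist,
         seasonal_amplitude = seasonal_amplitude, dispersion = dispersion),
    class = "generative_truth"
  )
}

#' Seasonal month-of-year factor
#'
#' Sinusoid peaking in July, normalised so the twelve month-of-year factors
#' average exactly 1 (a full cosine cycle sums to zero over 12 equally spaced
#' months).
#'
#' @param month `"YYYY-MM"` strings or integers 1--12.
#' @param amplitude seasonal amplitude in `[0, 1)`.
#' @return multiplicative factors, one per month.
#' @export
seasonal_factor <- function(month, amplitude = 0.25) {
  moy <- if (is.numeric(month)) as.integer(month) else month_of_year(month)
  stopifnot(all(moy >= 1L & moy <= 12L))
  1 + amplitude * cos(2 * pi * (moy - 7L) / 12)
}

#' Configuration of a synthetic study
#'
#' Bundles everything that determines a synthetic dataset: the territory, the
#' number of small areas, the study months, the cumulative event roll-out
#' schedule, the generative truth and the seed. Two calls with equal configs
#' produce byte-identical data.
#'
#' The default roll-out schedule grows superlinearly over the first four
#' years and linearly thereafter, emulating the real registry's two growth
#' phases.
#'
#' @param n_areas number of small areas (>= 10).
#' @param month_start,month_end inclusive month span, `"YYYY-MM"`.
#' @param n_events_by_year cumulative number of events at the end of each
#'   calendar year of the span; nondecreasing, first value >= 1. `NULL` for
#'   the default two-phase schedule.
#' @param bbox territory rectangle, named numeric
#'   `c(lon_min, lat_min, lon_max, lat_max)` in WGS84 decimal degrees.
#' @param truth a [generative_truth()].
#' @param seed integer seed; every generator is a pure function of
#'   (config, seed).
#' @param urban_fraction share of areas flagged urban.
#' @param n_cities number of urban cluster centres.
#' @param siting_bias terminal siting exponent b >= 0: event sites are drawn
#'   near areas with probability proportional to `pop_density^b`, with the
#'   exponent ramping from 0 in the first roll-out year to `siting_bias` in
#'   the last; 0 = unbiased siting throughout.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_areas = 3000,
                         month_start = "2010-01",
                         month_end = "2019-12",
                         n_events_by_year = NULL,
                         bbox = c(lon_min = -2.5, lat_min = 51, lon_max = 0.5, lat_max = 54),
                         truth = generative_truth(),
                         seed = 1L,
                         urban_fraction = 0.8,
                         n_cities = 5,
                         siting_bias = 0.5) {
  if (!is.numeric(n_areas) || n_areas < 10) {
    stop("`n_areas` must be at least 10 (quintile assignment needs 5 groups of >= 2)",
         call. = FALSE)
  }
  months <- month_seq(month_start, month_end)
  years <- sort(unique(month_year(months)))
  if (is.null(n_events_by_year)) {
    n_events_by_year <- default_event_schedule(length(years))
  }
  n_events_by_year <- as.integer(n_events_by_year)
  if (length(n_events_by_year) != length(years)) {
    stop("`n_events_by_year` must have one entry per calendar year of the month span (",
         length(years), ")", call. = FALSE)
  }
  if (n_events_by_year[1] < 1) {
    stop("schedule must launch at least one event in the first year ",
         "(distance to nearest event is undefined otherwise)", call. = FALSE)
  }
  if (is.unsorted(n_events_by_year)) {
    stop("`n_events_by_year` must be nondecreasing (cumulative schedule)", call. = FALSE)
  }
  stopifnot(length(bbox) == 4, bbox[["lon_min"]] < bbox[["lon_max"]],
            bbox[["lat_min"]] < bbox[["lat_max"]])
  stopifnot(inherits(truth, "generative_truth"))
  stopifnot(urban_fraction >= 0, urban_fraction <= 1, n_cities >= 1, siting_bias >= 0)
  structure(
    list(n_areas = as.integer(n_areas), month_start = month_start,
         month_end = month_end, months = months, years = years,
         n_events_by_year = n_events_by_year, bbox = bbox, truth = truth,
         seed = as.integer(seed), urban_fraction = urban_fraction,
         n_cities = as.integer(n_cities), siting_bias = siting_bias),
    class = "synth_config"
  )
}

## Two-phase cumulative schedule: quadratic ramp over the first four years,
## then a constant yearly increment. Calibrated to the default territory so
## the mean distance to the nearest event declines from the mid-30s of km in
## the first year to a few km by the final year.
default_event_schedule <- function(n_years) {
  ramp_years <- min(4L, n_years)
  ramp <- round(12 * (seq_len(ramp_years))^1.9)   # 12, 45, 96, 166
  if (n_years <= 4L) return(as.integer(ramp[seq_len(n_years)]))
  linear <- ramp[ramp_years] + 22L * seq_len(n_years - ramp_years)
  as.integer(c(ramp, linear))
}

## Scope a seed to a block without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
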