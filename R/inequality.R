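## Relative Index of Inequality (RII): regression-based ratio of the
## predicted outcome in the least deprived area to that in the most
## deprived area. 1 = no deprivation gradient. For distance, RII > 1 means
## less deprived areas are further from their nearest event; for
## participation, RII > 1 means less deprived areas participate more.

new_rii_result <- function(month, outcome, rii, fit, imd_min, imd_max) {
  if (!is.finite(rii) || rii <= 0) {
    stop("RII for ", outcome, " in ", month, " is not a positive number (",
         format(rii), "): predictions at the deprivation extremes are not ",
         "interpretable as a ratio", call. = FALSE)
  }
  tibble::tibble(
    month = month, outcome = outcome, rii = rii,
    model_intercept = unname(fit$coefficients[1]),
    model_slope = unname(fit$coefficients[2]),
    imd_min_used = imd_min, imd_max_used = imd_max
  )
}

#' RII in distance to the nearest event for one month
#'
#' Regresses that month's distance to the nearest event on the deprivation
#' score (linear model, deprivation as the only predictor) and returns the
#' ratio of the predicted distance at the observed minimum score (least
#' deprived area) to the predicted distance at the observed maximum score
#' (most deprived area).
#'
#' @param areas area tibble (needs `area_id`, `imd_score`).
#' @param distance_panel tibble from [build_distance_panel()].
#' @param month `"YYYY-MM"` month, covered by the panel.
#' @return one-row tibble: `month`, `outcome`, `rii`, `model_intercept`,
#'   `model_slope`, `imd_min_used`, `imd_max_used`.
#' @export
rii_distance <- function(areas, distance_panel, month) {
  month <- check_month(month)
  rows <- dplyr::inner_join(areas,
                            dplyr::filter(distance_panel, .data$month == !!month),
                            by = "area_id")
  if (nrow(rows) == 0) stop("month ", month, " not covered by the distance panel",
                            call. = FALSE)
  fit <- fit_ols(rows$imd_score, rows$distance_km)
  imd_min <- min(rows$imd_score)
  imd_max <- max(rows$imd_score)
  pred_min <- fit$coefficients[["intercept"]] + fit$coefficients[["slope"]] * imd_min
  pred_max <- fit$coefficients[["intercept"]] + fit$coefficients[["slope"]] * imd_max
  if (pred_min <= 0 || pred_max <= 0) {
    stop("predicted distance nonpositive at a deprivation extreme in ", month,
         " (", format(pred_min, digits = 4), " / ", format(pred_max, digits = 4),
         "): RII not interpretable", call. = FALSE)
  }
  new_rii_result(month, "distance", pred_min / pred_max, fit, imd_min, imd_max)
}

#' RII in participation for one month
#'
#' Fits a univariable Poisson regression with log link of that month's
#' finisher counts on the deprivation score, with log total population as
#' the offset, and returns the ratio of predicted rates at the deprivation
#' extremes. For the log-link model this ratio has the closed form
#' `exp(slope * (imd_min - imd_max))`, which is what is returned; with
#' deprivation increasing in the score, a negative slope gives RII > 1.
#'
#' Areas with zero population are excluded (the offset is undefined there)
#' with an informative message.
#'
#' @param areas area tibble (needs `area_id`, `imd_score`, `total_pop`).
#' @param finisher_panel tibble with `area_id`, `month`, `count`.
#' @param month `"YYYY-MM"` month, covered by the panel.
#' @inherit rii_distance return
#' @export
rii_participation <- function(areas, finisher_panel, month) {
  month <- check_month(month)
  rows <- dplyr::inner_join(areas,
                            dplyr::filter(finisher_panel, .data$month == !!month),
                            by = "area_id")
  if (nrow(rows) == 0) stop("month ", month, " not covered by the finisher panel",
                            call. = FALSE)
  zero_pop <- rows$total_pop <= 0
  if (any(zero_pop)) {
    rlang::inform(paste0("rii_participation: excluding ", sum(zero_pop),
                         " area(s) with zero population in ", month))
    rows <- rows[!zero_pop, , drop = FALSE]
  }
  X <- cbind(intercept = 1, imd_score = rows$imd_score)
  fit <- fit_poisson_glm(X, rows$count, offset = log(rows$total_pop))
  if (!fit$converged) {
    stop("participation RII model for ", month, " did not converge after ",
         fit$n_iterations, " IRLS iterations (deviance ",
         format(fit$deviance, digits = 6), ")", call. = FALSE)
  }
  imd_min <- min(rows$imd_score)
  imd_max <- max(rows$imd_score)
  rii <- exp(fit$coefficients[["imd_score"]] * (imd_min - imd_max))
  new_rii_result(month, "participation", rii, fit, imd_min, imd_max)
}

#' Monthly RII series
#'
#' One RII per month over `month_range`, for either outcome. Per-month
#' failures are re-signalled with the month label attached.
#'
#' @param areas area tibble.
#' @param panel the distance panel (`outcome = "distance"`) or finisher
#'   panel (`outcome = "participation"`).
#' @param month_range months to evaluate; defaults to all months present in
#'   the panel.
#' @param outcome `"distance"` or `"participation"`.
#' @return tibble of class `rii_series`, one row per month, ascending.
#' @export
rii_series <- function(areas, panel, month_range = NULL,
                       outcome = c("distance", "participation")) {
  outcome <- match.arg(outcome)
  if (is.null(month_range)) month_range <- sort(unique(panel$month))
  month_range <- sort(check_month(month_range))
  one <- if (outcome == "distance") rii_distance else rii_participation
  rows <- purrr::map(month_range, function(m) {
    tryCatch(one(areas, panel, m),
             error = function(e) {
               stop("RII (", outcome, ") failed for month ", m, ": ",
                    conditionMessage(e), call. = FALSE)
             })
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("rii_series", class(out))
  out
}

#' Plot an RII series
#'
#' Line plot of monthly RII with the no-gradient reference line at 1.
#'
#' @param object an `rii_series` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.rii_series <- function(object, ...) {
  df <- dplyr::mutate(object, date = month_mid_day(.data$month))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$date, y = .data$rii,
                                   colour = .data$outcome)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::labs(x = NULL, y = "Relative Index of Inequality",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.rii_series
#' @export
plot_rii_series <- function(object, ...) autoplot.rii_series(object, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
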