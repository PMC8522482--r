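test_that("quintile assignment splits ranked areas with remainder to lower quintiles", {
  a10 <- tibble::tibble(area_id = sprintf("Q%02d", 1:10), imd_score = (1:10) * 7)
  q10 <- assign_quintiles(a10)
  expect_equal(as.integer(table(q10$quintile)), rep(2L, 5))
  ## most deprived two areas land in quintile 5
  expect_equal(sort(q10$area_id[q10$quintile == 5]), c("Q09", "Q10"))

  a7 <- tibble::tibble(area_id = sprintf("S%02d", 1:7), imd_score = c(3, 9, 1, 7, 5, 8, 2))
  q7 <- assign_quintiles(a7)
  expect_equal(as.integer(table(q7$quintile)), c(2L, 2L, 1L, 1L, 1L))

  expect_error(assign_quintiles(a7[1:4, ]), "at least 5")
})

test_that("quintile sizes conserve areas and means increase with quintile", {
  areas <- generate_areas(synth_config(n_areas = 1000, month_start = "2010-01",
                                       month_end = "2010-12", n_events_by_year = 2,
                                       seed = 71))
  q <- assign_quintiles(areas)
  expect_equal(sum(table(q$quintile)), 1000L)
  expect_equal(as.integer(table(q$quintile)), rep(200L, 5))
  means <- dplyr::inner_join(areas, q, by = "area_id") |>
    dplyr::summarise(m = mean(imd_score), .by = quintile) |>
    dplyr::arrange(quintile)
  expect_true(all(diff(means$m) > 0))
})

test_that("score ties are broken deterministically by area id", {
  areas <- tibble::tibble(area_id = sprintf("T%02d", 10:1), imd_score = 5)
  q1 <- assign_quintiles(areas)
  q2 <- assign_quintiles(dplyr::arrange(areas, area_id))
  expect_identical(dplyr::arrange(q1, area_id), dplyr::arrange(q2, area_id))
  expect_equal(q1$quintile[q1$area_id == "T01"], 1L)
  expect_equal(q1$quintile[q1$area_id == "T10"], 5L)
})

test_that("one area per quintile reproduces that area's values", {
  areas <- tibble::tibble(area_id = sprintf("U%02d", 1:5),
                          imd_score = c(5, 20, 40, 60, 80),
                          total_pop = c(1000L, 2000L, 1000L, 4000L, 2500L))
  panel <- tibble::tibble(area_id = areas$area_id, month = "2010-01",
                          distance_km = c(1, 2, 4, 8, 16), nearest_event_id = "E")
  fp <- tibble::tibble(area_id = areas$area_id, month = "2010-01",
                       count = c(10L, 10L, 2L, 8L, 0L))
  qs <- quintile_series(areas, panel, fp, by = "month")
  for (i in 1:5) {
    row <- qs[qs$quintile == as.character(i), ]
    expect_equal(row$mean_distance_km, panel$distance_km[i])
    expect_equal(row$finishers_per_1000, 1000 * fp$count[i] / areas$total_pop[i])
  }
  overall <- qs[qs$quintile == "overall", ]
  expect_equal(overall$mean_distance_km, mean(panel$distance_km))
})

test_that("identical populations and counts equalise quintile rates", {
  areas <- tibble::tibble(area_id = sprintf("V%02d", 1:10),
                          imd_score = 1:10 * 9, total_pop = 1500L)
  panel <- tidyr::expand_grid(area_id = areas$area_id,
                              month = c("2010-01", "2010-02")) |>
    dplyr::mutate(distance_km = 3, nearest_event_id = "E")
  fp <- dplyr::mutate(panel[, c("area_id", "month")], count = 6L)
  qs <- quintile_series(areas, panel, fp, by = "month")
  expect_true(all(abs(qs$finishers_per_1000 - 1000 * 6 / 1500) < 1e-12))
})

test_that("the quintile series equals a brute-force group-by oracle", {
  ds <- tiny_dataset()
  qs <- quintile_series(ds$areas, ds$distance_panel, ds$finishers, by = "month")
  q <- assign_quintiles(ds$areas)
  joined <- ds$distance_panel |>
    dplyr::inner_join(ds$finishers, by = c("area_id", "month")) |>
    dplyr::inner_join(ds$areas[, c("area_id", "total_pop")], by = "area_id") |>
    dplyr::inner_join(q, by = "area_id")
  for (m in c("2010-05", "2011-11")) {
    sub <- joined[joined$month == m, ]
    for (k in 1:5) {
      g <- sub[sub$quintile == k, ]
      row <- qs[qs$period == m & qs$quintile == as.character(k), ]
      expect_equal(row$mean_distance_km, mean(g$distance_km), tolerance = 1e-12)
      expect_equal(row$finishers_per_1000, mean(1000 * g$count / g$total_pop),
                   tolerance = 1e-12)
    }
  }
})

test_that("yearly aggregation uses summed counts and mean within-year distance", {
  ds <- tiny_dataset()
  qs <- quintile_series(ds$areas, ds$distance_panel, ds$finishers, by = "year")
  expect_setequal(unique(qs$period), c("2010", "2011"))
  ## overall 2011 rate = unweighted mean over areas of 1000 * yearly count / pop
  per_area <- ds$finishers |>
    dplyr::filter(substr(month, 1, 4) == "2011") |>
    dplyr::summarise(count = sum(count), .by = area_id) |>
    dplyr::inner_join(ds$areas[, c("area_id", "total_pop")], by = "area_id")
  want <- mean(1000 * per_area$count / per_area$total_pop)
  got <- qs$finishers_per_1000[qs$period == "2011" & qs$quintile == "overall"]
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("with equal-sized quintiles the overall mean distance is the mean of quintile means", {
  areas <- generate_areas(synth_config(n_areas = 1000, month_start = "2010-01",
                                       month_end = "2010-12", n_events_by_year = 4,
                                       seed = 72))
  panel <- tibble::tibble(area_id = areas$area_id, month = "2010-01",
                          distance_km = runif(1000, 0, 50), nearest_event_id = "E")
  fp <- tibble::tibble(area_id = areas$area_id, month = "2010-01", count = 1L)
  qs <- quintile_series(areas, panel, fp, by = "month")
  m5 <- qs$mean_distance_km[qs$quintile != "overall"]
  expect_equal(mean(m5), qs$mean_distance_km[qs$quintile == "overall"],
               tolerance = 1e-12)
})

test_that("pooled rates differ from unweighted rates when populations vary", {
  areas <- tibble::tibble(area_id = c("W1", "W2", "W3", "W4", "W5"),
                          imd_score = c(10, 20, 30, 40, 50),
                          total_pop = c(1000L, 1000L, 1000L, 1000L, 5000L))
  panel <- tibble::tibble(area_id = areas$area_id, month = "2010-01",
                          distance_km = 1, nearest_event_id = "E")
  fp <- tibble::tibble(area_id = areas$area_id, month = "2010-01",
                       count = c(1L, 1L, 1L, 1L, 25L))
  un <- quintile_series(areas, panel, fp, by = "month")
  po <- quintile_series(areas, panel, fp, by = "month", pooled = TRUE)
  overall_un <- un$finishers_per_1000[un$quintile == "overall"]
  overall_po <- po$finishers_per_1000[po$quintile == "overall"]
  expect_equal(overall_un, mean(1000 * fp$count / areas$total_pop))
  expect_equal(overall_po, 1000 * sum(fp$count) / sum(areas$total_pop))
  expect_false(isTRUE(all.equal(overall_un, overall_po)))
})

test_that("panel summary reports type-7 order statistics", {
  one <- tibble::tibble(area_id = "A", imd_score = 12.5, ethnic_density = 3,
                        total_pop = 1500L, pop_density = 800)
  s1 <- panel_summary(one)
  expect_true(all(s1$mean == s1$min & s1$min == s1$median & s1$median == s1$max))

  five <- tibble::tibble(area_id = letters[1:5], imd_score = c(1, 2, 3, 4, 5))
  s5 <- panel_summary(five)
  expect_equal(s5$p25, 2)
  expect_equal(s5$median, 3)
  expect_equal(s5$p75, 4)

  x <- with_seed_test(73, rlnorm(1000, 3, 1))
  sx <- panel_summary(tibble::tibble(area_id = sprintf("x%04d", 1:1000),
                                     imd_score = x))
  ## independent type-7 oracle: manual linear interpolation of order stats
  xs <- sort(x)
  type7 <- function(p) {
    h <- (length(xs) - 1) * p + 1
    lo <- floor(h)
    xs[lo] + (h - lo) * (xs[lo + 1] - xs[lo])
  }
  expect_equal(sx$p25, type7(0.25), tolerance = 1e-12)
  expect_equal(sx$median, type7(0.5), tolerance = 1e-12)
  expect_equal(sx$p75, type7(0.75), tolerance = 1e-12)
  expect_true(sx$min <= sx$p25 && sx$p25 <= sx$median &&
                sx$median <= sx$p75 && sx$p75 <= sx$max)
})

test_that("quintile plotting returns a ggplot", {
  ds <- tiny_dataset()
  qs <- quintile_series(ds$areas, ds$distance_panel, ds$finishers, by = "month")
  p <- autoplot(qs, outcome = "participation")
  expect_s3_class(p, "ggplot")
})
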