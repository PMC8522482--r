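# Miniature synthetic study shared across test files: 50 areas, 24 months,
# 4 events. Built once per test run and cached.

tiny_config <- function(seed = 101,
                        truth = generative_truth(alpha = -3.2, beta_dist = -0.03),
                        ...) {
  synth_config(
    n_areas = 50,
    month_start = "2010-01", month_end = "2011-12",
    n_events_by_year = c(2, 4),
    seed = seed,
    truth = truth,
    ...
  )
}

.fixture_cache <- new.env(parent = emptyenv())

tiny_dataset <- function() {
  if (is.null(.fixture_cache$tiny)) {
    .fixture_cache$tiny <- simulate_dataset(tiny_config())
  }
  .fixture_cache$tiny
}

# Hand-built 4-point registry with known coordinates and staggered launches.
toy_registry <- function() {
  tibble::tibble(
    event_id = c("E1", "E2", "E3", "E4"),
    lat = c(52.0, 52.5, 53.0, 51.5),
    lon = c(-1.0, -0.5, 0.0, -1.5),
    launch_date = as.Date(c("2010-01-01", "2010-06-10", "2011-02-14", "2011-09-01")),
    closure_date = as.Date(c(NA, NA, NA, NA))
  )
}

toy_areas <- function(n = 8, seed = 5) {
  with_seed_test(seed, tibble::tibble(
    area_id = sprintf("T%02d", seq_len(n)),
    lat = runif(n, 51, 54),
    lon = runif(n, -2, 0.5),
    imd_score = runif(n, 1, 95),
    total_pop = sample(1000:3000, n, replace = TRUE),
    ethnic_density = runif(n, 0, 60),
    pop_density = exp(runif(n, 4, 9)),
    urban_flag = runif(n) < 0.7
  ))
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(code)
}

# O(A*E*M) reference: nearest active event by exhaustive double loop.
brute_force_panel <- function(areas, registry, months) {
  rows <- list()
  for (m in months) {
    date15 <- as.Date(paste0(m, "-15"))
    act <- registry[registry$launch_date <= date15 &
                      (is.na(registry$closure_date) | registry$closure_date > date15), ]
    act <- act[order(act$event_id), ]
    for (i in seq_len(nrow(areas))) {
      best_d <- Inf
      best_id <- NA_character_
      for (j in seq_len(nrow(act))) {
        d <- geodesic_km(areas$lat[i], areas$lon[i], act$lat[j], act$lon[j])
        if (d < best_d) {
          best_d <- d
          best_id <- act$event_id[j]
        }
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        area_id = areas$area_id[i], month = m,
        distance_km = best_d, nearest_event_id = best_id
      )
    }
  }
  dplyr::arrange(dplyr::bind_rows(rows), month, area_id)
}
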