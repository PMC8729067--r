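test_that("weather generation is deterministic and respects its knobs", {
  s <- weather_spec(lat_range = c(40, 42), lon_range = c(-94, -93),
                    dates = seq(as.Date("2005-11-01"), by = "day",
                                length.out = 20))
  w1 <- simulate_weather(s, seed = 7)
  w2 <- simulate_weather(s, seed = 7)
  expect_identical(w1, w2)
  w3 <- simulate_weather(s, seed = 8)
  expect_false(identical(w1$temp, w3$temp))

  expect_true(all(w1$snow >= 0))
  expect_true(all(w1$cloud >= 0 & w1$cloud <= 100))

  # zero snowfall rate: snow identically zero
  s0 <- weather_spec(lat_range = c(40, 42), lon_range = c(-94, -93),
                     dates = seq(as.Date("2005-11-01"), by = "day",
                                 length.out = 20),
                     snowfall_rate = 0, base_temp_c = -5)
  expect_true(all(simulate_weather(s0, seed = 1)$snow == 0))

  # pure linear trend: day 31 is exactly 6 degC below day 1
  st <- weather_spec(lat_range = c(40, 42), lon_range = c(-94, -93),
                     dates = seq(as.Date("2005-09-01"), by = "day",
                                 length.out = 31),
                     trend_c_per_day = -0.2, ar1_sd = 0,
                     grad_c_per_deglat = 0)
  wt <- simulate_weather(st, seed = 1)
  cell1 <- wt[wt$cell_id == 1, ]
  expect_equal(cell1$temp[31], cell1$temp[1] - 6)

  expect_error(weather_spec(dates = as.Date(character())), "dates")
})

test_that("direct choice-set generation follows the Gumbel-argmax model", {
  # beta = 0, s = 0: every position equally likely
  t0 <- truth_parameters("temp", beta = 0, s = 0)
  pan <- simulate_choice_sets(t0, n_individuals = 7000, seed = 21)
  freq <- table(pan$drawn_index[pan$chosen == 1]) / 7000
  expect_true(all(abs(freq - 1 / 7) < 3 * sqrt((1 / 7) * (6 / 7) / 7000)))

  # huge beta: alternative with the largest covariate always chosen
  tb <- truth_parameters("temp", beta = 500, s = 0)
  panb <- simulate_choice_sets(tb, n_individuals = 200, seed = 3)
  by_set <- split(seq_len(nrow(panb)), panb$set_id)
  always_max <- vapply(by_set, function(i) {
    panb$chosen[i][which.max(panb$temp[i])] == 1
  }, logical(1))
  expect_true(all(always_max))

  # determinism
  expect_identical(simulate_choice_sets(tb, 50, seed = 5),
                   simulate_choice_sets(tb, 50, seed = 5))

  expect_error(truth_parameters(c("temp", "snow"), beta = 1),
               regexp = "length")
})

test_that("Gumbel-argmax frequencies match softmax probabilities", {
  # MC oracle: with fixed beta, the chance that the alternative ranked r by
  # covariate value wins equals its conditional-logit probability; compare
  # the summed indicator with its Poisson-binomial expectation.
  tr <- truth_parameters("temp", beta = 1, s = 0)
  n <- 1e5
  pan <- simulate_choice_sets(tr, n_individuals = n, seed = 77)
  z <- matrix(pan$temp, nrow = 7)
  chosen <- matrix(pan$chosen == 1, nrow = 7)
  r_rank <- apply(z, 2, rank, ties.method = "first")
  p <- apply(z, 2, function(x) {
    e <- exp(x - max(x))
    e / sum(e)
  })
  for (r in c(1, 4, 7)) {
    sel <- r_rank == r
    obs <- sum(chosen[sel])
    expected <- sum(p[sel])
    se <- sqrt(sum(p[sel] * (1 - p[sel])))
    expect_lt(abs(obs - expected), 3 * se)
  }
})

test_that("scheduled tracks force an exact number of qualifying departures", {
  fx <- scheduled_fixture(n_birds = 5, n_departures = 8, seed = 12)
  daily <- collapse_daily(fx$records)
  rel <- find_relocations(daily)
  expect_equal(nrow(rel), 8)
  expect_identical(
    paste(rel$bird_id, rel$date),
    with(dplyr::filter(fx$records, scheduled_departure),
         paste(bird_id, as.Date(timestamp, tz = "UTC"))))

  # empty and deterministic cases
  w <- fx$weather
  expect_equal(nrow(simulate_tracks(w, n_birds = 0)), 0)
  t1 <- simulate_tracks(w, n_birds = 2, departures = 1, seed = 9,
                        start_lat_range = c(42.5, 43.5),
                        start_lon_range = c(-94, -92.5))
  t2 <- simulate_tracks(w, n_birds = 2, departures = 1, seed = 9,
                        start_lat_range = c(42.5, 43.5),
                        start_lon_range = c(-94, -92.5))
  expect_identical(t1, t2)
  expect_error(simulate_tracks(w, n_birds = 1,
                               start_lat_range = c(70, 71)),
               "outside the weather grid")
  # timestamps strictly increasing per bird
  ok <- tapply(t1$timestamp, t1$bird_id, function(x) !is.unsorted(x,
                                                                  strictly = TRUE))
  expect_true(all(ok))
})

test_that("stochastic departure mode produces plausible southward tracks", {
  w <- tiny_weather(n_days = 50, seed = 6, lat_range = c(38, 44),
                    lon_range = c(-95, -91), base_temp_c = 2,
                    trend_c_per_day = -0.3)
  tr <- simulate_tracks(w, n_birds = 4, departures = NULL, seed = 31,
                        start_lat_range = c(42.5, 43.5),
                        start_lon_range = c(-94, -92.5))
  expect_gt(nrow(tr), 0)
  first_last <- tr |>
    dplyr::group_by(bird_id) |>
    dplyr::summarise(dlat = dplyr::last(lat) - dplyr::first(lat))
  expect_true(all(first_last$dlat <= 0.02)) # jitter never exceeds ~2 km
})
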