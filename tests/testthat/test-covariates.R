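test_that("grid matching finds the nearest cell centre with documented ties", {
  w <- tiny_weather(n_days = 2, seed = 1)
  cells <- attr(w, "cells")
  # a point exactly at a centre maps to that cell
  i <- 17
  expect_equal(match_grid_cell(cells$lat[i], cells$lon[i], w), cells$cell_id[i])
  # clearly closer to one centre
  expect_equal(match_grid_cell(cells$lat[1] + 0.01, cells$lon[1] + 0.01, w),
               cells$cell_id[1])
  # exact tie between two lon-neighbours resolves to the lower id
  mid_lon <- (cells$lon[1] + cells$lon[2]) / 2
  expect_equal(match_grid_cell(cells$lat[1], mid_lon, w), cells$cell_id[1])
  expect_error(match_grid_cell(10, 0, w), "outside the weather grid")
})

test_that("wind splits into head/tail by the 120-degree arc about 162 deg", {
  # air moving due south (heading 180) is inside 162 +/- 60: tailwind
  expect_equal(classify_wind(0, -5), tibble::tibble(head = 0, tail = 5))
  # due north: headwind
  expect_equal(classify_wind(0, 5), tibble::tibble(head = 5, tail = 0))
  # calm air
  expect_equal(classify_wind(0, 0), tibble::tibble(head = 0, tail = 0))
  # boundary heading 102 deg is inclusive tailwind; 101.9 is headwind
  sp <- 3
  u <- sp * sin(102 * pi / 180); v <- sp * cos(102 * pi / 180)
  expect_equal(classify_wind(u, v)$tail, sp)
  u2 <- sp * sin(101.9 * pi / 180); v2 <- sp * cos(101.9 * pi / 180)
  expect_equal(classify_wind(u2, v2)$head, sp)
  # speed preserved, one-sided, for random vectors
  set.seed(4)
  uu <- rnorm(50, 0, 5); vv <- rnorm(50, 0, 5)
  cw <- classify_wind(uu, vv)
  expect_equal(cw$head + cw$tail, sqrt(uu^2 + vv^2))
  expect_true(all(cw$head * cw$tail == 0))
})

test_that("frost and snow-day counters follow the stated reset rules", {
  rc <- run_counters(c(-1, -2, -3), c(0, 0, 0), c(1, 1, 1))
  expect_equal(rc$frost, c(1L, 2L, 3L))
  rc <- run_counters(c(-1, 1, -1), c(0, 0, 0), c(1, 1, 1))
  expect_equal(rc$frost, c(1L, 0L, 1L))
  rc <- run_counters(c(-1, -1, -1), c(0, 0, 0), c(1, 1, 2))
  expect_equal(rc$frost, c(1L, 2L, 1L)) # reset on episode change, then count
  # a day at exactly 0 degC holds the counter
  rc <- run_counters(c(-1, 0, -1), c(0, 0, 0), c(1, 1, 1))
  expect_equal(rc$frost, c(1L, 1L, 2L))

  rc <- run_counters(c(-1, -1), c(0.03, 0.03), c(1, 1))
  expect_equal(rc$snow, c(1L, 2L))
  rc <- run_counters(-1, 0.02, 1)
  expect_equal(rc$snow, 0L)
  rc <- run_counters(c(-1, -1, -1), c(0.03, 0.01, 0.03), c(1, 1, 1))
  expect_equal(rc$snow, c(1L, 0L, 1L))
  st <- cumulative_state()
  expect_error(update_snow_days(st, -0.1, 1), "nonnegative")
  st <- migchoice:::advance_state(st, -1, 0, 1, as.Date("2005-10-02"))
  expect_error(update_frost_days(st, -1, 1, as.Date("2005-10-01")),
               "time order")
})

test_that("ice accrues at 1 cm per 3.3 FDD after a 2-day trigger and melts at 1 cm per 1.3 TDD", {
  rc <- run_counters(c(-5, -5, -3.3), c(0, 0, 0), c(1, 1, 1))
  expect_equal(rc$thickness, c(0, 0, 1))
  expect_equal(rc$ice, c(FALSE, FALSE, TRUE))
  # one day at +1.3 degC melts the 1 cm and resets the tracker
  rc <- run_counters(c(-5, -5, -3.3, 1.3), c(0, 0, 0, 0), c(1, 1, 1, 1))
  expect_equal(rc$thickness[4], 0)
  expect_false(rc$ice[4])
  # never freezes above zero
  rc <- run_counters(rep(5, 10), rep(0, 10), rep(1, 10))
  expect_true(all(!rc$ice))
  # episode change wipes accumulated ice
  rc <- run_counters(c(-5, -5, -5, -5), c(0, 0, 0, 0), c(1, 1, 1, 2))
  expect_false(rc$ice[4])
})

test_that("incremental counters match whole-sequence recomputation on random sequences", {
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(5:25, 1)
    temps <- round(rnorm(n, -0.5, 3), 1)
    temps[sample(n, max(1, n %/% 6))] <- 0 # exercise the hold rule
    depths <- round(pmax(rnorm(n, 0.02, 0.03), 0), 3)
    episodes <- cumsum(c(1, runif(n - 1) < 0.15))
    inc <- run_counters(temps, depths, episodes)
    expect_equal(inc$frost, oracle_frost(temps, episodes))
    expect_equal(inc$snow, oracle_snow(depths, episodes))
    orc <- oracle_ice(temps, episodes)
    expect_equal(inc$ice, orc$cover)
    expect_equal(inc$thickness, orc$thickness)
  }
})

test_that("assembled covariates use presence-fill across gaps and reset on relocation", {
  # constant freezing weather on a tiny grid
  w <- tiny_weather(n_days = 20, seed = 3, base_temp_c = -6,
                    trend_c_per_day = 0, grad_c_per_deglat = 0, ar1_sd = 0,
                    snowfall_rate = 0)
  lat0 <- 41; lon0 <- -93
  # records on days 1, 2 then a 3-day recording gap to day 6; then a >=30 km
  # relocation on day 7 and arrival residence on day 8
  far <- lat0 - 40 / 111.19
  rec <- make_records(
    "b1",
    c("2005-09-01 06:00", "2005-09-02 06:00", "2005-09-06 06:00",
      "2005-09-07 06:00", "2005-09-07 18:00", "2005-09-08 06:00"),
    lat = c(lat0, lat0, lat0, lat0, far, far),
    lon = rep(lon0, 6))
  daily <- collapse_daily(rec)
  lab <- label_residency(daily, lat_col = "start_lat", lon_col = "start_lon")
  cov <- assemble_covariates(lab, w)
  # day 2 -> 2 frost days; the 3-day gap credits presence: day 6 -> 6
  expect_equal(cov$frost_days, c(1L, 2L, 6L, 7L, 1L))
  # relocation day (day 7) still reports the origin's counters; the first
  # record at the new site starts from scratch
  expect_equal(cov$episode, c(1L, 1L, 1L, 1L, 2L))
  # pressure difference: 0 for the first record by convention
  expect_equal(cov$press_diff[1], 0)
  w2 <- w[w$cell_id == cov$cell_id[1], ]
  expect_equal(cov$press_diff[2],
               w2$pressure[w2$date == cov$date[2]] -
                 w2$pressure[w2$date == cov$date[1]])
  # missing weather triggers a named error
  wshort <- w[w$date <= as.Date("2005-09-05"), ]
  attr(wshort, "cells") <- attr(w, "cells")
  expect_error(assemble_covariates(lab, wshort), "missing weather")
})

test_that("2-SD standardization centres, halves the SD, and inverts", {
  d <- tibble::tibble(temp = c(0, 1, 2))
  std <- standardize_covariates(d, cols = "temp")
  expect_equal(std$data$temp, c(-0.5, 0, 0.5))
  set.seed(8)
  d2 <- tibble::tibble(temp = rnorm(100, 3, 2), snow = rexp(100))
  s2 <- standardize_covariates(d2, cols = c("temp", "snow"))
  expect_equal(vapply(s2$data[c("temp", "snow")], mean, 1),
               c(temp = 0, snow = 0))
  expect_equal(vapply(s2$data[c("temp", "snow")], sd, 1),
               c(temp = 0.5, snow = 0.5))
  back <- unstandardize_covariates(s2$data, s2$scaling)
  expect_equal(back$temp, d2$temp, tolerance = 1e-12)
  expect_equal(back$snow, d2$snow, tolerance = 1e-12)
  expect_error(standardize_covariates(tibble::tibble(temp = rep(1, 5)),
                                      cols = "temp"), "zero-variance")
})
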