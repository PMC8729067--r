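# Fixtures are generated in code; nothing is read from disk.

tiny_weather <- function(n_days = 30, seed = 2,
                         lat_range = c(40, 43), lon_range = c(-94, -92),
                         ...) {
  spec <- weather_spec(
    lat_range = lat_range, lon_range = lon_range,
    dates = seq(as.Date("2005-09-01"), by = "day", length.out = n_days),
    ...)
  simulate_weather(spec, seed = seed)
}

# Scheduled multi-bird fixture: known number of qualifying departures.
scheduled_fixture <- function(n_birds = 6, n_departures = 10, seed = 4,
                              n_days = 60) {
  w <- tiny_weather(n_days = n_days, seed = seed,
                    lat_range = c(38, 44), lon_range = c(-95, -91))
  tr <- simulate_tracks(
    w, n_birds = n_birds,
    departures = allocate_departures(n_birds, n_departures),
    residence_days = 7, start_lat_range = c(42.5, 43.5),
    start_lon_range = c(-94, -92.5), step_km_range = c(50, 110),
    start_window_days = 5, seed = seed)
  list(weather = w, records = tr)
}

# Hand-built raw records: one bird, fixed positions/times.
make_records <- function(bird_id, times, lat, lon, sex = "female") {
  tibble::tibble(bird_id = bird_id, sex = sex,
                 timestamp = as.POSIXct(times, tz = "UTC"),
                 lat = lat, lon = lon, valid = TRUE)
}

# Whole-sequence recomputations of the cumulative counters: for each day,
# rescan the full history from the start of the current episode.
oracle_frost <- function(temps, episodes) {
  n <- length(temps)
  out <- integer(n)
  for (t in seq_len(n)) {
    cnt <- 0L
    for (i in seq_len(t)) {
      if (episodes[i] != episodes[t]) {
        cnt <- 0L
      } else if (temps[i] < 0) {
        cnt <- cnt + 1L
      } else if (temps[i] > 0) {
        cnt <- 0L
      }
    }
    out[t] <- cnt
  }
  out
}

oracle_snow <- function(depths, episodes, threshold = 0.0254) {
  n <- length(depths)
  out <- integer(n)
  for (t in seq_len(n)) {
    cnt <- 0L
    for (i in seq_len(t)) {
      if (episodes[i] != episodes[t] || depths[i] < threshold) {
        cnt <- 0L
      } else {
        cnt <- cnt + 1L
      }
    }
    out[t] <- cnt
  }
  out
}

oracle_ice <- function(temps, episodes) {
  n <- length(temps)
  cover <- logical(n)
  thick_out <- numeric(n)
  for (t in seq_len(n)) {
    trig <- 0L; thick <- 0; had <- FALSE
    for (i in seq_len(t)) {
      if (i > 1 && episodes[i] != episodes[i - 1]) {
        trig <- 0L; thick <- 0; had <- FALSE
      }
      if (temps[i] < 0) {
        trig <- trig + 1L
        if (trig > 2 || thick > 0) thick <- thick - temps[i] / 3.3
      } else if (temps[i] > 0) {
        thick <- max(0, thick - temps[i] / 1.3)
        if (thick == 0) trig <- 0L
      }
      if (had && thick < 1) {
        thick <- 0; trig <- 0L; had <- FALSE
      }
      if (thick >= 1) had <- TRUE
    }
    cover[t] <- thick >= 1
    thick_out[t] <- thick
  }
  list(cover = cover, thickness = thick_out)
}

# Run the incremental updaters over a sequence and collect outputs.
run_counters <- function(temps, depths, episodes) {
  st <- cumulative_state()
  n <- length(temps)
  frost <- integer(n); snowd <- integer(n); ice <- logical(n)
  thick <- numeric(n)
  d0 <- as.Date("2005-09-01")
  for (i in seq_len(n)) {
    st <- migchoice:::advance_state(st, temps[i], depths[i], episodes[i],
                                    d0 + i - 1)
    frost[i] <- st$frost_days
    snowd[i] <- st$snow_days
    ice[i] <- st$ice_cover
    thick[i] <- st$ice_thickness_cm
  }
  list(frost = frost, snow = snowd, ice = ice, thickness = thick)
}
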