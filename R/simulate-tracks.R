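#' Simulate multi-bird autumn migration tracks
#'
#' Generates southward tracks over a simulated weather grid: each bird
#' starts at a northern location and accrues two daily fixes (06:00 and
#' 18:00 UTC) while in residence; on a departure day the evening fix lies
#' a migration-scale step (>= 30 km, with a southward component) from the
#' morning fix, after which the bird takes up residence at the new site.
#'
#' Two departure mechanisms are available:
#'
#' * **Scheduled** (`departures` given): each bird performs a fixed number
#'   of departures, each preceded by `residence_days` residence records,
#'   so that downstream processing yields an exact, known number of
#'   qualifying relocation events and choice sets. Observed departures in
#'   the real system are conditioned on, not generated, so a stochastic
#'   generator cannot guarantee counts; this mode exists to pin them.
#' * **Stochastic** (`departures = NULL`): after a warm-up of
#'   `residence_days` days, each further residence day is a choice between
#'   "depart today" and staying, decided by Gumbel-argmax over the
#'   utilities (under the bird's coefficient draw from `truth`) of the
#'   current day versus the `J - 1` most recent days. This is a
#'   constructed stand-in for an unobserved departure process, not an
#'   estimated model.
#'
#' @param weather Weather grid from [simulate_weather()]; must cover the
#'   simulated region and dates.
#' @param n_birds Number of birds (0 allowed; returns an empty tibble).
#' @param departures Integer vector (length `n_birds`, recycled) of
#'   scheduled departures per bird, or `NULL` for stochastic departures.
#' @param residence_days Residence records before each departure
#'   (default 7, so each departure has at least 6 preceding
#'   non-relocation records).
#' @param truth [truth_parameters()] used by the stochastic mechanism
#'   (ignored when scheduled).
#' @param start_lat_range,start_lon_range Ranges for initial positions;
#'   defaults sit in the northern part of the default grid.
#' @param step_km_range Range of departure step lengths, km.
#' @param start_window_days Birds begin their first residence uniformly
#'   within this many days of the weather start date (default 75, so
#'   departures fall throughout the September-December migration window
#'   and late birds experience winter onset).
#' @param seed Integer seed.
#' @param J Set size used by the stochastic mechanism's recent-day
#'   comparison (default 7).
#' @return Tibble of location records: `bird_id`, `sex`, `timestamp`
#'   (POSIXct UTC), `lat`, `lon`, `valid`, plus a logical
#'   `scheduled_departure` marking the morning fix of each scheduled
#'   departure day (all `FALSE` in stochastic mode until a departure is
#'   drawn).
#' @export
simulate_tracks <- function(weather, n_birds, departures = NULL,
                            residence_days = 7, truth = winter_truth(),
                            start_lat_range = c(44, 48),
                            start_lon_range = c(-94.5, -91.5),
                            step_km_range = c(60, 180),
                            start_window_days = 75, seed = 1L, J = 7) {
  cells <- grid_cells(weather)
  dates <- sort(unique(weather$date))
  if (n_birds == 0) {
    return(tibble::tibble(bird_id = character(), sex = character(),
                          timestamp = as.POSIXct(character(), tz = "UTC"),
                          lat = numeric(), lon = numeric(), valid = logical(),
                          scheduled_departure = logical()))
  }
  if (start_lat_range[1] < min(cells$lat) - 1 ||
      start_lat_range[2] > max(cells$lat) + 1 ||
      start_lon_range[1] < min(cells$lon) - 1 ||
      start_lon_range[2] > max(cells$lon) + 1) {
    stop("bird start region lies outside the weather grid", call. = FALSE)
  }
  set.seed(seed)
  if (!is.null(departures)) {
    departures <- rep_len(as.integer(departures), n_birds)
  }
  sexes <- sample(c("female", "male"), n_birds, replace = TRUE,
                  prob = c(0.9, 0.1))

  km_per_deglat <- 111.19
  one_bird <- function(b) {
    lat <- runif(1, start_lat_range[1], start_lat_range[2])
    lon <- runif(1, start_lon_range[1], start_lon_range[2])
    start_day <- 1 + sample.int(start_window_days, 1) - 1
    day <- start_day
    rows <- list()
    jitter <- function(x) x + runif(1, -0.004, 0.004)
    add_day <- function(day, lat1, lon1, lat2, lon2, dep) {
      d <- dates[day]
      rows[[length(rows) + 1]] <<- tibble::tibble(
        timestamp = as.POSIXct(paste(d, c("06:00:00", "18:00:00")),
                               tz = "UTC"),
        lat = c(lat1, lat2), lon = c(lon1, lon2),
        scheduled_departure = c(dep, FALSE)
      )
    }
    step_south <- function(lat, lon) {
      step <- runif(1, step_km_range[1], step_km_range[2])
      # heading near the migration direction; always southward
      brg <- runif(1, 135, 190)
      dlat <- -abs(step * cos((180 - brg) * pi / 180)) / km_per_deglat
      dlon <- step * sin((brg - 180) * pi / 180) /
        (km_per_deglat * cos(lat * pi / 180))
      c(max(lat + dlat, min(cells$lat) + 0.5),
        min(max(lon + dlon, min(cells$lon) + 0.5), max(cells$lon) - 0.5))
    }

    if (!is.null(departures)) {
      n_dep <- departures[b]
      for (dep in seq_len(max(n_dep, 0))) {
        for (r in seq_len(residence_days)) {
          if (day > length(dates)) break
          add_day(day, jitter(lat), jitter(lon), jitter(lat), jitter(lon),
                  FALSE)
          day <- day + 1
        }
        if (day > length(dates) - 1) break
        dest <- step_south(lat, lon)
        add_day(day, lat, lon, dest[1], dest[2], TRUE)
        day <- day + 1
        lat <- dest[1]; lon <- dest[2]
      }
      # trailing residence so the last departure has a following record
      for (r in seq_len(min(3, length(dates) - day + 1))) {
        add_day(day, jitter(lat), jitter(lon), jitter(lat), jitter(lon),
                FALSE)
        day <- day + 1
      }
    } else {
      b_a <- truth$beta + truth$s * rnorm(length(truth$beta))
      state <- cumulative_state()
      recent_u <- numeric(0)
      while (day <= length(dates) - 1) {
        cell <- match_grid_cell(lat, lon, weather)
        w <- weather[weather$cell_id == cell & weather$date == dates[day], ]
        state <- advance_state(state, w$temp, w$snow, 1L, dates[day])
        wind <- classify_wind(w$u_wind, w$v_wind)
        z <- c(temp = w$temp, snow = w$snow, press_diff = 0,
               precip = w$precip, cloud = w$cloud, head = wind$head,
               tail = wind$tail, frost_days = state$frost_days,
               snow_days = state$snow_days,
               ice_cover = as.numeric(state$ice_cover))
        u_today <- sum(z[truth$covariates] * b_a)
        recent_u <- c(tail(recent_u, J - 2), u_today)
        depart <- length(recent_u) >= J - 1 &&
          which.max(recent_u + rgumbel(length(recent_u))) ==
            length(recent_u)
        if (depart) {
          dest <- step_south(lat, lon)
          add_day(day, lat, lon, dest[1], dest[2], TRUE)
          lat <- dest[1]; lon <- dest[2]
          state <- cumulative_state()
          recent_u <- numeric(0)
        } else {
          add_day(day, jitter(lat), jitter(lon), jitter(lat), jitter(lon),
                  FALSE)
        }
        day <- day + 1
      }
    }
    out <- dplyr::bind_rows(rows)
    out$bird_id <- sprintf("bird_%03d", b)
    out$sex <- sexes[b]
    out$valid <- TRUE
    out
  }

  dplyr::bind_rows(lapply(seq_len(n_birds), one_bird)) |>
    dplyr::select("bird_id", "sex", "timestamp", "lat", "lon", "valid",
                  "scheduled_departure")
}

#' Allocate a total number of departures across birds
#'
#' Deterministic helper for scheduled-track fixtures: spreads
#' `n_departures` over `n_birds` with at most `max_per_bird` each, filling
#' round-robin so counts differ by at most one beyond the first pass
#' (e.g. 73 departures over 43 birds gives 13 birds with 1 and 30 birds
#' with 2).
#'
#' @param n_birds,n_departures Counts.
#' @param max_per_bird Cap per bird (default 4).
#' @return Integer vector of length `n_birds` summing to `n_departures`.
#' @export
allocate_departures <- function(n_birds, n_departures, max_per_bird = 4) {
  stopifnot(n_departures <= n_birds * max_per_bird)
  alloc <- rep(0L, n_birds)
  i <- 1L
  for (k in seq_len(n_departures)) {
    while (alloc[i] >= max_per_bird) i <- if (i == n_birds) 1L else i + 1L
    alloc[i] <- alloc[i] + 1L
    i <- if (i == n_birds) 1L else i + 1L
  }
  alloc
}
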