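#' Great-circle distance between coordinate pairs
#'
#' Haversine distance on a sphere of radius 6371 km, the standard metric for
#' telemetry tracks at the tens-to-hundreds of km scale (difference from an
#' ellipsoidal distance is below 0.5\%).
#'
#' @param lat1,lon1,lat2,lon2 Numeric vectors of decimal degrees (WGS84).
#'   Recycled to a common length.
#' @return Numeric vector of distances in kilometres.
#' @examples
#' gc_distance_km(45, -93, 44, -93) # one degree of latitude, ~111.2 km
#' @export
gc_distance_km <- function(lat1, lon1, lat2, lon2) {
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371000) / 1000
}

check_coords <- function(lat, lon) {
  bad <- !is.finite(lat) | !is.finite(lon) | abs(lat) > 90 | abs(lon) > 180
  if (any(bad)) {
    stop("invalid coordinates: lat must lie in [-90, 90], lon in [-180, 180]",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Collapse raw location records to one movement per bird per day
#'
#' High recording frequency can mask long daily movements, so successive
#' records are combined to at most a single movement per UTC calendar day:
#' for each bird-day with two or more fixes, a straight-line movement from
#' the day's first recorded position to its last is assumed. Days with a
#' single fix yield a stationary record (distance 0). Records flagged
#' invalid are dropped first, and the fraction excised is reported as an
#' attribute.
#'
#' @param records Data frame with columns `bird_id`, `timestamp` (POSIXct,
#'   UTC), `lat`, `lon`, and optionally `valid` (logical) and `sex`.
#'   Must be time-sorted within each bird; unsorted input is an error
#'   rather than being silently reordered.
#' @return A tibble with one row per bird per day: `bird_id`, `date`,
#'   `start_lat`, `start_lon`, `end_lat`, `end_lon`, `distance_km`,
#'   `southward` (end latitude strictly below start), `n_fixes`,
#'   `first_time`, `last_time`, and `gap_to_next_h` (hours from this day's
#'   last fix to the bird's next day's first fix; `NA` for the final
#'   record). Attribute `excised_fraction` gives the share of valid raw
#'   records absorbed by the collapse.
#' @export
collapse_daily <- function(records) {
  stopifnot(all(c("bird_id", "timestamp", "lat", "lon") %in% names(records)))
  if (!inherits(records$timestamp, "POSIXct")) {
    stop("timestamp must be POSIXct", call. = FALSE)
  }
  if ("valid" %in% names(records)) {
    records <- dplyr::filter(records, .data$valid)
  }
  check_coords(records$lat, records$lon)
  unsorted <- records |>
    dplyr::group_by(.data$bird_id) |>
    dplyr::summarise(ok = !is.unsorted(.data$timestamp), .groups = "drop")
  if (any(!unsorted$ok)) {
    stop("records are not time-sorted within bird(s): ",
         paste(unsorted$bird_id[!unsorted$ok], collapse = ", "),
         call. = FALSE)
  }

  daily <- records |>
    dplyr::mutate(date = as.Date(.data$timestamp, tz = "UTC")) |>
    dplyr::group_by(.data$bird_id, .data$date) |>
    dplyr::summarise(
      start_lat = dplyr::first(.data$lat),
      start_lon = dplyr::first(.data$lon),
      end_lat = dplyr::last(.data$lat),
      end_lon = dplyr::last(.data$lon),
      n_fixes = dplyr::n(),
      first_time = dplyr::first(.data$timestamp),
      last_time = dplyr::last(.data$timestamp),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      distance_km = gc_distance_km(.data$start_lat, .data$start_lon,
                                   .data$end_lat, .data$end_lon),
      southward = .data$end_lat < .data$start_lat
    ) |>
    dplyr::arrange(.data$bird_id, .data$date) |>
    dplyr::group_by(.data$bird_id) |>
    dplyr::mutate(
      gap_to_next_h = as.numeric(difftime(dplyr::lead(.data$first_time),
                                          .data$last_time, units = "hours"))
    ) |>
    dplyr::ungroup() |>
    dplyr::relocate("distance_km", "southward", .after = "end_lon")

  n_raw <- nrow(records)
  attr(daily, "excised_fraction") <-
    if (n_raw > 0) (n_raw - nrow(daily)) / n_raw else 0
  daily
}

#' Identify migration-scale relocation events
#'
#' A daily movement qualifies as the start of a migration-scale relocation
#' when it meets all four criteria: (1) movement distance at least
#' `min_km`; (2) date inside the autumn migration window; (3) time gap to
#' the bird's next record at most `max_gap_h`; and (4) a southward
#' component (end latitude strictly below start latitude).
#'
#' @param daily Output of [collapse_daily()].
#' @param min_km Minimum movement distance in km (default 30, the
#'   empirical breakpoint between local and migration flights).
#' @param window Character vector of two month-day strings `"mm-dd"`
#'   bounding the migration period, inclusive (default 1 Sep - 31 Dec).
#' @param max_gap_h Maximum hours to the next record (default 48).
#' @return Tibble of events: `bird_id`, `date`, `origin_lat`, `origin_lon`,
#'   `dest_lat`, `dest_lon`, `distance_km`. All four criteria are asserted
#'   on the output.
#' @export
find_relocations <- function(daily, min_km = 30,
                             window = c("09-01", "12-31"),
                             max_gap_h = 48) {
  md <- format(daily$date, "%m-%d")
  in_window <- md >= window[1] & md <= window[2]
  ev <- daily |>
    dplyr::mutate(.in_window = in_window) |>
    dplyr::filter(
      .data$distance_km >= min_km,
      .data$.in_window,
      !is.na(.data$gap_to_next_h) & .data$gap_to_next_h <= max_gap_h,
      .data$southward
    ) |>
    dplyr::transmute(
      bird_id = .data$bird_id, date = .data$date,
      origin_lat = .data$start_lat, origin_lon = .data$start_lon,
      dest_lat = .data$end_lat, dest_lon = .data$end_lon,
      distance_km = .data$distance_km
    )
  stopifnot(all(ev$distance_km >= min_km), all(ev$dest_lat < ev$origin_lat))
  ev
}

#' Label residency episodes along a track
#'
#' A bird is considered to have changed location when it has moved a
#' cumulative straight distance of at least `radius_km` from the anchor of
#' its current residency episode (i.e. left a circle of that radius around
#' the last anchoring location). The record that triggers the change
#' becomes the anchor of the next episode. Positions are taken from the
#' `lat`/`lon` columns named by `lat_col`/`lon_col`, so the function works
#' on raw fixes or on collapsed daily records (e.g. start-of-day
#' positions, so that a departure day still belongs to the episode it
#' departs from).
#'
#' @param records Time-sorted data frame with `bird_id` and coordinate
#'   columns.
#' @param radius_km Episode radius in km (default 30).
#' @param lat_col,lon_col Names of the coordinate columns.
#' @return The input with an integer `episode` column (1-based, per bird,
#'   non-decreasing in time) plus `anchor_lat`/`anchor_lon` of the current
#'   episode.
#' @export
label_residency <- function(records, radius_km = 30,
                            lat_col = "lat", lon_col = "lon") {
  stopifnot(lat_col %in% names(records), lon_col %in% names(records))
  lab_one <- function(df) {
    n <- nrow(df)
    lat <- df[[lat_col]]
    lon <- df[[lon_col]]
    ep <- integer(n)
    a_lat <- numeric(n)
    a_lon <- numeric(n)
    cur <- 1L
    ai <- 1L
    for (i in seq_len(n)) {
      if (i > 1 &&
          gc_distance_km(lat[ai], lon[ai], lat[i], lon[i]) >= radius_km) {
        cur <- cur + 1L
        ai <- i
      }
      ep[i] <- cur
      a_lat[i] <- lat[ai]
      a_lon[i] <- lon[ai]
    }
    df$episode <- ep
    df$anchor_lat <- a_lat
    df$anchor_lon <- a_lon
    df
  }
  records |>
    dplyr::group_by(.data$bird_id) |>
    dplyr::group_modify(~ lab_one(.x)) |>
    dplyr::ungroup()
}
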