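#' Match points to nearest weather-grid cells
#'
#' Nearest-neighbour assignment of locations to grid cells by great-circle
#' distance to the cell centres. For a regular lat/lon grid the nearest
#' centre is found by index snapping and then verified against the 3x3
#' neighbourhood; exact ties go to the lowest cell id (documented
#' convention).
#'
#' @param lat,lon Numeric vectors of point coordinates.
#' @param grid A weather grid from [simulate_weather()], or any object with
#'   a `cells` attribute holding a data frame of `cell_id`, `lat`, `lon`
#'   centres on a regular lat/lon lattice.
#' @return Integer vector of cell ids.
#' @export
match_grid_cell <- function(lat, lon, grid) {
  cells <- grid_cells(grid)
  lats <- sort(unique(cells$lat))
  lons <- sort(unique(cells$lon))
  dlat <- if (length(lats) > 1) min(diff(lats)) else 1
  dlon <- if (length(lons) > 1) min(diff(lons)) else 1
  out_of_range <- lat < min(lats) - 1.5 * dlat | lat > max(lats) + 1.5 * dlat |
    lon < min(lons) - 1.5 * dlon | lon > max(lons) + 1.5 * dlon
  if (any(out_of_range)) {
    i <- which(out_of_range)[1]
    stop(sprintf("point (%.4f, %.4f) lies outside the weather grid",
                 lat[i], lon[i]), call. = FALSE)
  }
  # cell_id is row-major over (lat index, lon index); verified at build time
  n_lon <- length(lons)
  ix_lat <- pmin(pmax(round((lat - lats[1]) / dlat) + 1, 1), length(lats))
  ix_lon <- pmin(pmax(round((lon - lons[1]) / dlon) + 1, 1), n_lon)
  best_id <- integer(length(lat))
  best_d <- rep(Inf, length(lat))
  for (di in -1:1) {
    for (dj in -1:1) {
      ii <- pmin(pmax(ix_lat + di, 1), length(lats))
      jj <- pmin(pmax(ix_lon + dj, 1), n_lon)
      id <- (ii - 1L) * n_lon + jj
      d <- gc_distance_km(lat, lon, lats[ii], lons[jj])
      take <- d < best_d - 1e-9 | (abs(d - best_d) <= 1e-9 & id < best_id)
      best_d[take] <- d[take]
      best_id[take] <- id[take]
    }
  }
  best_id
}

grid_cells <- function(grid) {
  cells <- attr(grid, "cells")
  if (is.null(cells)) stop("grid lacks a 'cells' attribute", call. = FALSE)
  cells
}

#' Classify a wind vector into head- and tailwind speed
#'
#' The zonal (`u`) and meridional (`v`) components follow the reanalysis
#' convention of the direction *toward which* the air moves. The vector
#' heading (compass degrees) is compared with the mean relocation heading;
#' winds within `half_arc` degrees to either side push the bird along its
#' track and are classified as tailwind, the rest as headwind. The full
#' wind speed is assigned to the matching component and the other is set
#' to 0. The arc boundary is inclusive for tailwind.
#'
#' @param u,v Wind components in m/s (vectors, recycled).
#' @param reference_heading Migration heading in compass degrees
#'   (default 162, the mean direction of observed relocations).
#' @param half_arc Half-width of the tailwind arc in degrees (default 60).
#' @return Tibble with columns `head` and `tail` (m/s); exactly one of the
#'   two is nonzero unless the wind is calm, and `head + tail` equals the
#'   wind speed.
#' @export
classify_wind <- function(u, v, reference_heading = 162, half_arc = 60) {
  stopifnot(all(is.finite(u)), all(is.finite(v)))
  speed <- sqrt(u^2 + v^2)
  heading <- (atan2(u, v) * 180 / pi) %% 360
  delta <- abs((heading - reference_heading + 180) %% 360 - 180)
  is_tail <- delta <= half_arc & speed > 0
  tibble::tibble(
    head = ifelse(is_tail, 0, speed),
    tail = ifelse(is_tail, speed, 0)
  )
}

#' @name cumulative-state
#' @title Cumulative winter-condition state updaters
#'
#' @description
#' Per-bird running counters of experienced winter severity, advanced one
#' day at a time in chronological order:
#'
#' * **Frost days** count consecutive days of mean temperature below
#'   0 degC at one location; moving to a new residency episode or a day above
#'   0 degC resets the counter. A day at exactly 0 degC neither increments nor
#'   resets (the counter holds).
#' * **Snow days** count consecutive days of snow depth at or above
#'   2.54 cm (1 inch), reset by a shallower day or an episode change.
#' * **Ice cover** tracks estimated thin-ice thickness on shallow water:
#'   formation is triggered after two consecutive calendar days below
#'   0 degC, after which ice grows by 1 cm per 3.3 freezing degree-days and
#'   melts by 1 cm per 1.3 thawing degree-days; cover is present while
#'   thickness is at least 1 cm, and thickness and trigger reset when the
#'   estimate drops back below 1 cm or the bird changes episode.
#'
#' `cumulative_state()` builds the initial state; each updater returns the
#' modified state. Days must be supplied in time order; out-of-order dates
#' are an error.
#'
#' @param state A state list from `cumulative_state()`.
#' @param mean_temp Daily mean temperature, degC.
#' @param snow_depth Daily snow depth, m (nonnegative).
#' @param episode Residency episode id for the day.
#' @param date Optional date of the observation, used to enforce time order.
#' @return `cumulative_state()` returns the state list with fields
#'   `frost_days`, `snow_days`, `ice_thickness_cm`, `freeze_trigger`,
#'   `ice_cover`, `had_cover`, `episode`, `last_date`; updaters return the
#'   updated list.
NULL

#' @rdname cumulative-state
#' @export
cumulative_state <- function() {
  list(frost_days = 0L, snow_days = 0L, ice_thickness_cm = 0,
       freeze_trigger = 0L, ice_cover = FALSE, had_cover = FALSE,
       episode = NA_integer_, last_date = as.Date(NA))
}

check_state_day <- function(state, episode, date) {
  if (!is.null(date) && !is.na(state$last_date) && date <= state$last_date) {
    stop("cumulative updaters must be called in time order", call. = FALSE)
  }
  !is.na(state$episode) && !identical(as.integer(episode),
                                      as.integer(state$episode))
}

#' @rdname cumulative-state
#' @export
update_frost_days <- function(state, mean_temp, episode, date = NULL) {
  changed <- check_state_day(state, episode, date)
  if (changed) state$frost_days <- 0L
  if (mean_temp < 0) {
    state$frost_days <- state$frost_days + 1L
  } else if (mean_temp > 0) {
    state$frost_days <- 0L
  } # exactly 0 degC: hold
  state
}

#' @rdname cumulative-state
#' @export
update_snow_days <- function(state, snow_depth, episode, date = NULL,
                             threshold_m = 0.0254) {
  if (snow_depth < 0) stop("snow depth must be nonnegative", call. = FALSE)
  changed <- check_state_day(state, episode, date)
  if (changed) state$snow_days <- 0L
  if (snow_depth >= threshold_m) {
    state$snow_days <- state$snow_days + 1L
  } else {
    state$snow_days <- 0L
  }
  state
}

#' @rdname cumulative-state
#' @export
update_ice <- function(state, mean_temp, episode, date = NULL,
                       fdd_per_cm = 3.3, tdd_per_cm = 1.3,
                       cover_cm = 1, trigger_days = 2L) {
  changed <- check_state_day(state, episode, date)
  if (changed) {
    state$ice_thickness_cm <- 0
    state$freeze_trigger <- 0L
    state$had_cover <- FALSE
  }
  if (mean_temp < 0) {
    state$freeze_trigger <- state$freeze_trigger + 1L
    if (state$freeze_trigger > trigger_days || state$ice_thickness_cm > 0) {
      state$ice_thickness_cm <- state$ice_thickness_cm - mean_temp / fdd_per_cm
    }
  } else if (mean_temp > 0) {
    state$ice_thickness_cm <-
      max(0, state$ice_thickness_cm - mean_temp / tdd_per_cm)
    if (state$ice_thickness_cm == 0) state$freeze_trigger <- 0L
  } # exactly 0 degC: hold
  if (state$had_cover && state$ice_thickness_cm < cover_cm) {
    state$ice_thickness_cm <- 0
    state$freeze_trigger <- 0L
    state$had_cover <- FALSE
  }
  state$ice_cover <- state$ice_thickness_cm >= cover_cm
  if (state$ice_cover) state$had_cover <- TRUE
  state
}

advance_state <- function(state, mean_temp, snow_depth, episode, date = NULL) {
  state <- update_frost_days(state, mean_temp, episode, date)
  state <- update_snow_days(state, snow_depth, episode, date)
  state <- update_ice(state, mean_temp, episode, date)
  state$episode <- as.integer(episode)
  if (!is.null(date)) state$last_date <- date
  state
}

#' Assemble per-record daily covariates
#'
#' Matches each collapsed daily record to its weather-grid cell (by the
#' day's start-of-day position, the bird's decision context) and computes
#' the ten model covariates: temperature, snow depth, barometric pressure
#' difference to the previous record, precipitation, cloud cover, head-
#' and tailwind speed, and the cumulative frost-day, snow-day and
#' ice-cover indices.
#'
#' When the interval between two successive records spans multiple
#' calendar days and both bounding records belong to the same residency
#' episode, the bird is assumed to have remained at the earlier record's
#' location for the whole gap, and the cumulative counters advance through
#' the intervening days using that location's weather. Counters reset on
#' residency-episode change. The pressure difference of a bird's first
#' record is 0 by convention (neutral under centering).
#'
#' @param daily Collapsed daily records ([collapse_daily()]) carrying an
#'   `episode` column ([label_residency()] on start-of-day positions).
#' @param weather Weather grid from [simulate_weather()] (or any tibble of
#'   `cell_id`, `date`, `temp`, `snow`, `precip`, `cloud`, `pressure`,
#'   `u_wind`, `v_wind` with a `cells` attribute).
#' @param reference_heading,half_arc Wind-arc parameters for
#'   [classify_wind()].
#' @param snow_threshold_m Snow-day depth threshold (default 0.0254 m).
#' @return The input records with covariate columns `temp`, `snow`,
#'   `press_diff`, `precip`, `cloud`, `head`, `tail`, `frost_days`,
#'   `snow_days`, `ice_cover` (0/1) appended.
#' @export
assemble_covariates <- function(daily, weather, reference_heading = 162,
                                half_arc = 60, snow_threshold_m = 0.0254) {
  stopifnot("episode" %in% names(daily))
  cells <- grid_cells(weather)
  daily <- dplyr::arrange(daily, .data$bird_id, .data$date)
  daily$cell_id <- match_grid_cell(daily$start_lat, daily$start_lon, weather)

  # fast weather lookup: key on cell_id x date
  wx <- weather
  wx_key <- paste(wx$cell_id, wx$date)
  lookup <- function(cell, date) {
    i <- match(paste(cell, date), wx_key)
    if (any(is.na(i))) {
      miss <- paste(cell[is.na(i)], date[is.na(i)], sep = " @ ")
      stop("missing weather for cell-day(s): ",
           paste(unique(miss), collapse = ", "), call. = FALSE)
    }
    wx[i, , drop = FALSE]
  }

  one_bird <- function(df) {
    n <- nrow(df)
    state <- cumulative_state()
    frost <- integer(n); snowd <- integer(n); ice <- integer(n)
    prev_press <- NA_real_
    press_diff <- numeric(n)
    w_rec <- lookup(df$cell_id, df$date)
    for (i in seq_len(n)) {
      if (i > 1) {
        gap_dates <- seq(df$date[i - 1] + 1, df$date[i], by = "day")
        gap_dates <- head(gap_dates, -1)
        if (length(gap_dates) > 0 && df$episode[i] == df$episode[i - 1]) {
          # presence fill at the earlier record's end-of-day location
          fill_cell <- match_grid_cell(df$end_lat[i - 1], df$end_lon[i - 1],
                                       weather)
          wfill <- lookup(rep(fill_cell, length(gap_dates)), gap_dates)
          for (g in seq_along(gap_dates)) {
            state <- advance_state(state, wfill$temp[g], wfill$snow[g],
                                   df$episode[i], gap_dates[g])
          }
        }
      }
      state <- advance_state(state, w_rec$temp[i], w_rec$snow[i],
                             df$episode[i], df$date[i])
      frost[i] <- state$frost_days
      snowd[i] <- state$snow_days
      ice[i] <- as.integer(state$ice_cover)
      press_diff[i] <- if (is.na(prev_press)) 0 else w_rec$pressure[i] - prev_press
      prev_press <- w_rec$pressure[i]
    }
    wind <- classify_wind(w_rec$u_wind, w_rec$v_wind,
                          reference_heading, half_arc)
    df$temp <- w_rec$temp
    df$snow <- w_rec$snow
    df$press_diff <- press_diff
    df$precip <- w_rec$precip
    df$cloud <- w_rec$cloud
    df$head <- wind$head
    df$tail <- wind$tail
    df$frost_days <- frost
    df$snow_days <- snowd
    df$ice_cover <- ice
    df
  }

  daily |>
    dplyr::group_by(.data$bird_id) |>
    dplyr::group_modify(~ one_bird(.x)) |>
    dplyr::ungroup()
}

#' The ten departure-model covariates
#' @return Character vector of covariate column names.
#' @export
covariate_names <- function() {
  c("temp", "snow", "press_diff", "precip", "cloud", "head", "tail",
    "frost_days", "snow_days", "ice_cover")
}

#' Standardize covariates by two standard deviations
#'
#' Centres each column on its mean and divides by twice its standard
#' deviation, so a coefficient represents the change in utility for a
#' 2-SD increase of the covariate and coefficients of continuous and
#' binary inputs are roughly comparable. By default the binary ice
#' indicator is rescaled like every other covariate; set
#' `center_only` to names of columns that should only be centred.
#'
#' @param data Data frame containing the covariate columns.
#' @param cols Columns to standardize (default [covariate_names()]
#'   intersected with `data`).
#' @param center_only Optional character vector of columns to centre
#'   without rescaling.
#' @param scaling Optional scaling tibble from a previous call, to apply
#'   existing constants (e.g. to a prediction grid).
#' @return List with `data` (the input with the named columns replaced by
#'   standardized values) and `scaling` (tibble of `covariate`, `mean`,
#'   `sd`, `divisor`).
#' @export
standardize_covariates <- function(data, cols = NULL, center_only = character(),
                                   scaling = NULL) {
  if (is.null(cols)) cols <- intersect(covariate_names(), names(data))
  stopifnot(length(cols) > 0, all(cols %in% names(data)), nrow(data) > 0)
  if (is.null(scaling)) {
    mu <- vapply(data[cols], mean, numeric(1))
    sg <- vapply(data[cols], sd, numeric(1))
    if (any(sg == 0)) {
      stop("zero-variance covariate(s): ",
           paste(cols[sg == 0], collapse = ", "), call. = FALSE)
    }
    div <- ifelse(cols %in% center_only, 1, 2 * sg)
    scaling <- tibble::tibble(covariate = cols, mean = mu, sd = sg,
                              divisor = div)
  }
  for (k in seq_len(nrow(scaling))) {
    cv <- scaling$covariate[k]
    if (cv %in% names(data)) {
      data[[cv]] <- (data[[cv]] - scaling$mean[k]) / scaling$divisor[k]
    }
  }
  list(data = data, scaling = scaling)
}

#' Invert a 2-SD standardization
#'
#' @param data Data frame with standardized covariate columns.
#' @param scaling Scaling tibble from [standardize_covariates()].
#' @return The data with the named columns mapped back to the raw scale.
#' @export
unstandardize_covariates <- function(data, scaling) {
  for (k in seq_len(nrow(scaling))) {
    cv <- scaling$covariate[k]
    if (cv %in% names(data)) {
      data[[cv]] <- data[[cv]] * scaling$divisor[k] + scaling$mean[k]
    }
  }
  data
}
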