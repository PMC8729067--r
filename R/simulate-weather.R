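#' Specification for a synthetic gridded weather field
#'
#' Describes a regular lat/lon grid of roughly `cell_km` spacing and the
#' statistical structure of its daily fields: a linear seasonal cooling
#' trend plus a latitudinal temperature gradient with AR(1) day-to-day
#' noise per cell; episodic snowfall that accumulates while the cell is
#' below freezing and melts at a constant rate above freezing; and
#' independent daily wind, precipitation, cloud and surface-pressure
#' draws. This emulates the marginal behaviour of a regional-reanalysis
#' product at the 32 x 32 km scale without any atmospheric physics.
#'
#' @param lat_range,lon_range Numeric length-2 vectors, degrees.
#' @param cell_km Cell spacing in km (> 0; default 32).
#' @param dates Date vector (or length-2 range) of daily time steps.
#' @param base_temp_c Mean temperature (degC) on the first day at the grid's
#'   central latitude.
#' @param trend_c_per_day Seasonal temperature trend, degC/day (negative in
#'   autumn).
#' @param grad_c_per_deglat Temperature change per degree of latitude
#'   northward (negative: north is colder).
#' @param ar1_coef,ar1_sd AR(1) coefficient (in `[0, 1)`) and innovation SD
#'   (degC) of the per-cell temperature noise.
#' @param snowfall_rate Mean snowfall events per cell-day (Poisson).
#' @param snowfall_depth_m Mean depth per event, m (exponential).
#' @param melt_m_per_day Snow melt rate while temperature exceeds 0 degC.
#' @param wind_sd SD of each wind component, m/s.
#' @param precip_prob,precip_mean Probability of a wet day and mean daily
#'   precipitation (kg/m2) on wet days.
#' @param pressure_mean,pressure_sd Surface pressure mean and SD, Pa.
#' @return A `weather_spec` list, validated.
#' @export
weather_spec <- function(lat_range = c(33, 50), lon_range = c(-97, -89),
                         cell_km = 32,
                         dates = seq(as.Date("2005-09-01"),
                                     as.Date("2005-12-31"), by = "day"),
                         base_temp_c = 14, trend_c_per_day = -0.15,
                         grad_c_per_deglat = -0.8,
                         ar1_coef = 0.65, ar1_sd = 3.5,
                         snowfall_rate = 0.05, snowfall_depth_m = 0.06,
                         melt_m_per_day = 0.02,
                         wind_sd = 4, precip_prob = 0.3, precip_mean = 2,
                         pressure_mean = 101300, pressure_sd = 400) {
  if (length(dates) == 2 && dates[1] < dates[2]) {
    dates <- seq(dates[1], dates[2], by = "day")
  }
  spec <- list(lat_range = lat_range, lon_range = lon_range, cell_km = cell_km,
               dates = as.Date(dates), base_temp_c = base_temp_c,
               trend_c_per_day = trend_c_per_day,
               grad_c_per_deglat = grad_c_per_deglat,
               ar1_coef = ar1_coef, ar1_sd = ar1_sd,
               snowfall_rate = snowfall_rate,
               snowfall_depth_m = snowfall_depth_m,
               melt_m_per_day = melt_m_per_day, wind_sd = wind_sd,
               precip_prob = precip_prob, precip_mean = precip_mean,
               pressure_mean = pressure_mean, pressure_sd = pressure_sd)
  stopifnot(cell_km > 0, length(spec$dates) >= 1,
            ar1_coef >= 0, ar1_coef < 1, ar1_sd >= 0,
            snowfall_rate >= 0, melt_m_per_day >= 0,
            diff(lat_range) > 0, diff(lon_range) > 0)
  class(spec) <- "weather_spec"
  spec
}

#' Simulate a gridded daily weather field
#'
#' Draws daily fields for every cell and date of a [weather_spec()]:
#' temperature as seasonal trend + latitude gradient + per-cell AR(1)
#' noise; snow depth accumulating from Poisson snowfall events while the
#' cell is below freezing and melting at the stated rate above freezing
#' (never negative); independent u/v wind, precipitation, cloud (clamped
#' to `[0, 100]`\%) and surface pressure. Reproducible given `seed`.
#'
#' @param spec A [weather_spec()].
#' @param seed Integer seed.
#' @return Tibble with columns `cell_id`, `lat`, `lon`, `date`, `temp`,
#'   `snow`, `precip`, `cloud`, `pressure`, `u_wind`, `v_wind`; cell
#'   centre geometry in attribute `cells`, the spec in attribute `spec`.
#' @export
simulate_weather <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "weather_spec"))
  km_per_deglat <- 111.19
  dlat <- spec$cell_km / km_per_deglat
  mid_lat <- mean(spec$lat_range)
  dlon <- spec$cell_km / (km_per_deglat * cos(mid_lat * pi / 180))
  lats <- seq(spec$lat_range[1], spec$lat_range[2], by = dlat)
  lons <- seq(spec$lon_range[1], spec$lon_range[2], by = dlon)
  if (length(lats) == 0 || length(lons) == 0 || length(spec$dates) == 0) {
    stop("empty grid or date range", call. = FALSE)
  }
  # row-major ids over (lat index, lon index), matching match_grid_cell()
  cells <- tibble::tibble(
    cell_id = seq_len(length(lats) * length(lons)),
    lat = rep(lats, each = length(lons)),
    lon = rep(lons, times = length(lats))
  )
  n_cells <- nrow(cells)
  n_days <- length(spec$dates)

  set.seed(seed)
  sd_stat <- spec$ar1_sd / sqrt(max(1 - spec$ar1_coef^2, 1e-12))
  noise <- matrix(0, n_cells, n_days)
  noise[, 1] <- rnorm(n_cells, 0, sd_stat)
  if (n_days > 1) {
    for (d in 2:n_days) {
      noise[, d] <- spec$ar1_coef * noise[, d - 1] +
        rnorm(n_cells, 0, spec$ar1_sd)
    }
  }
  day_index <- seq_len(n_days) - 1
  temp <- outer(rep(1, n_cells), spec$base_temp_c +
                  spec$trend_c_per_day * day_index) +
    outer(spec$grad_c_per_deglat * (cells$lat - mid_lat), rep(1, n_days)) +
    noise

  snow <- matrix(0, n_cells, n_days)
  depth <- rep(0, n_cells)
  for (d in seq_len(n_days)) {
    events <- rpois(n_cells, spec$snowfall_rate)
    fall <- ifelse(events > 0 & temp[, d] < 0,
                   rexp(n_cells, 1 / max(spec$snowfall_depth_m, 1e-12)) *
                     events, 0)
    depth <- depth + fall
    melt <- ifelse(temp[, d] > 0, spec$melt_m_per_day, 0)
    depth <- pmax(depth - melt, 0)
    snow[, d] <- depth
  }

  n <- n_cells * n_days
  u <- rnorm(n, 0, spec$wind_sd)
  v <- rnorm(n, 0, spec$wind_sd)
  precip <- ifelse(runif(n) < spec$precip_prob,
                   rexp(n, 1 / max(spec$precip_mean, 1e-12)), 0)
  cloud <- pmin(pmax(rnorm(n, 50, 30), 0), 100)
  pressure <- rnorm(n, spec$pressure_mean, spec$pressure_sd)

  out <- tibble::tibble(
    cell_id = rep(cells$cell_id, times = n_days),
    lat = rep(cells$lat, times = n_days),
    lon = rep(cells$lon, times = n_days),
    date = rep(spec$dates, each = n_cells),
    temp = as.vector(temp),
    snow = as.vector(snow),
    precip = precip,
    cloud = cloud,
    pressure = pressure,
    u_wind = u,
    v_wind = v
  )
  attr(out, "cells") <- cells
  attr(out, "spec") <- spec
  out
}
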