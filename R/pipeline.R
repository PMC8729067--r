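#' Run the full departure-choice pipeline
#'
#' Chains the processing stages: collapse raw fixes to daily movements,
#' identify migration-scale relocations, label residency episodes (on
#' start-of-day positions, so a departure day belongs to the episode it
#' leaves), attach the ten weather covariates, build temporal choice sets
#' and 2-SD-standardize the covariates over the panel's alternatives.
#'
#' @param records Raw location records (`bird_id`, `timestamp`, `lat`,
#'   `lon`, optional `valid`, `sex`).
#' @param weather Weather grid from [simulate_weather()].
#' @param J Choice-set size (default 7).
#' @param min_km,window,max_gap_h Relocation criteria
#'   ([find_relocations()]).
#' @param reference_heading,half_arc Wind-arc parameters.
#' @param standardize Standardize covariates over the panel (default
#'   `TRUE`).
#' @return List: `panel` (long-form choice panel, standardized), `scaling`
#'   (tibble of constants, or `NULL`), `records` (per-day covariate table,
#'   raw scale, with `relocation` flag), `relocations`, `summary`
#'   ([summarize_sets()]).
#' @export
departure_panel <- function(records, weather, J = 7, min_km = 30,
                            window = c("09-01", "12-31"), max_gap_h = 48,
                            reference_heading = 162, half_arc = 60,
                            standardize = TRUE) {
  daily <- collapse_daily(records)
  rel <- find_relocations(daily, min_km = min_km, window = window,
                          max_gap_h = max_gap_h)
  lab <- label_residency(daily, radius_km = min_km,
                         lat_col = "start_lat", lon_col = "start_lon")
  cov <- assemble_covariates(lab, weather,
                             reference_heading = reference_heading,
                             half_arc = half_arc)
  cov$relocation <- paste(cov$bird_id, cov$date) %in%
    paste(rel$bird_id, rel$date)
  panel <- build_choice_sets(cov, J = J)
  scaling <- NULL
  if (standardize && nrow(panel) > 0) {
    std <- standardize_covariates(panel)
    panel <- std$data
    scaling <- std$scaling
  }
  list(panel = panel, scaling = scaling, records = cov,
       relocations = rel, summary = summarize_sets(panel))
}
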