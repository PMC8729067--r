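#' Build temporal choice sets around each relocation
#'
#' For every relocation record, the choice set pairs the observed
#' departure day (the chosen alternative, always last) with the `J - 1`
#' non-relocation records of the same bird directly preceding it. By
#' default the preceding records must also postdate the bird's previous
#' relocation, so every alternative describes the decision context at the
#' departure site's residency spell; set `within_previous_relocation =
#' FALSE` to allow histories to reach across earlier relocations. Small
#' local moves never break a set. A relocation with fewer than `J - 1`
#' qualifying predecessors yields no set. Because records need not be on
#' consecutive days, a set may span more than `J` calendar days.
#'
#' @param records Time-sorted per-bird daily records with a logical (or
#'   0/1) `relocation` column and covariate columns attached.
#' @param J Set size (>= 2; default 7).
#' @param within_previous_relocation Restrict alternatives to records
#'   after the bird's previous relocation (default `TRUE`).
#' @return Long-form choice panel tibble: `set_id`, `bird_id`,
#'   `alt_index` (1..J in time order, chosen last), `date`, `chosen`
#'   (0/1), and all other input columns. Invariants (one chosen per set,
#'   chosen last, J rows per set) are asserted.
#' @export
build_choice_sets <- function(records, J = 7,
                              within_previous_relocation = TRUE) {
  if (J < 2) stop("J must be at least 2", call. = FALSE)
  stopifnot(all(c("bird_id", "date", "relocation") %in% names(records)))
  records <- dplyr::arrange(records, .data$bird_id, .data$date)

  one_bird <- function(df) {
    idx <- which(as.logical(df$relocation))
    sets <- list()
    for (r in idx) {
      lower <- 0L
      if (within_previous_relocation) {
        prev <- idx[idx < r]
        if (length(prev) > 0) lower <- max(prev)
      }
      cand <- which(seq_len(nrow(df)) < r & seq_len(nrow(df)) > lower &
                      !as.logical(df$relocation))
      if (length(cand) >= J - 1) {
        pick <- tail(cand, J - 1)
        rows <- df[c(pick, r), , drop = FALSE]
        rows$alt_index <- seq_len(J)
        rows$chosen <- c(rep(0L, J - 1), 1L)
        sets[[length(sets) + 1]] <- rows
      }
    }
    if (length(sets) == 0) return(df[0, , drop = FALSE])
    dplyr::bind_rows(sets, .id = ".set_in_bird")
  }

  panel <- records |>
    dplyr::group_by(.data$bird_id) |>
    dplyr::group_modify(~ one_bird(.x)) |>
    dplyr::ungroup()
  if (nrow(panel) == 0) {
    return(tibble::tibble(set_id = integer(), bird_id = character(),
                          alt_index = integer(), date = as.Date(character()),
                          chosen = integer()))
  }
  panel <- panel |>
    dplyr::mutate(set_id = cumsum(.data$alt_index == 1)) |>
    dplyr::select(-".set_in_bird") |>
    dplyr::relocate("set_id", "bird_id", "alt_index", "date", "chosen")

  by_set <- panel |>
    dplyr::group_by(.data$set_id) |>
    dplyr::summarise(n = dplyr::n(), n_chosen = sum(.data$chosen),
                     last_chosen = .data$chosen[dplyr::n()] == 1,
                     .groups = "drop")
  stopifnot(all(by_set$n == J), all(by_set$n_chosen == 1),
            all(by_set$last_chosen))
  panel
}

#' Summarize a choice panel
#'
#' @param panel Long-form choice panel ([build_choice_sets()] or
#'   [simulate_choice_sets()]).
#' @return List with `n_sets`, `n_alternatives`, `n_individuals`,
#'   `sets_per_individual` (tibble of per-bird counts and their mean),
#'   and `span_days` (tibble of per-set calendar span, first to last
#'   alternative inclusive, when a `date` column is present). An empty
#'   panel yields zeros.
#' @export
summarize_sets <- function(panel) {
  if (nrow(panel) == 0) {
    return(list(n_sets = 0L, n_alternatives = 0L, n_individuals = 0L,
                sets_per_individual = tibble::tibble(bird_id = character(),
                                                     n_sets = integer()),
                span_days = tibble::tibble(set_id = integer(),
                                           span = integer())))
  }
  per_ind <- panel |>
    dplyr::distinct(.data$bird_id, .data$set_id) |>
    dplyr::count(.data$bird_id, name = "n_sets")
  span <- if ("date" %in% names(panel)) {
    panel |>
      dplyr::group_by(.data$set_id) |>
      dplyr::summarise(
        span = as.integer(max(.data$date) - min(.data$date)) + 1L,
        .groups = "drop")
  } else {
    tibble::tibble(set_id = unique(panel$set_id), span = NA_integer_)
  }
  list(
    n_sets = dplyr::n_distinct(panel$set_id),
    n_alternatives = nrow(panel),
    n_individuals = dplyr::n_distinct(panel$bird_id),
    sets_per_individual = per_ind,
    span_days = span
  )
}
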