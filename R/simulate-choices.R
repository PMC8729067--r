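#' Generating ("truth") parameters for the departure-choice model
#'
#' Population mean coefficients and between-individual standard deviations
#' of the random utility coefficients, on the 2-SD-standardized covariate
#' scale. Each individual's coefficient vector is drawn from
#' N(beta, diag(s^2)).
#'
#' @param covariates Character vector of covariate names (a subset of
#'   [covariate_names()]).
#' @param beta Numeric vector of population means, one per covariate.
#' @param s Numeric vector of between-individual SDs (nonnegative).
#' @return A `truth_parameters` list.
#' @export
truth_parameters <- function(covariates, beta, s = rep(0, length(beta))) {
  stopifnot(length(covariates) == length(beta), length(beta) == length(s),
            all(s >= 0), !anyDuplicated(covariates),
            all(covariates %in% covariate_names()))
  structure(list(covariates = covariates,
                 beta = setNames(as.numeric(beta), covariates),
                 s = setNames(as.numeric(s), covariates)),
            class = "truth_parameters")
}

#' Winter-conditions truth parameters
#'
#' Default generating values for simulation studies: the estimated
#' winter-conditions model for autumn-migrating mallards (temperature,
#' snow depth, frost days, snow days, ice cover), on the 2-SD covariate
#' scale.
#'
#' @return A [truth_parameters()] object.
#' @export
winter_truth <- function() {
  truth_parameters(
    covariates = c("temp", "snow", "frost_days", "snow_days", "ice_cover"),
    beta = c(-6.04, 5.23, 3.71, 10.61, 1.65),
    s = c(9.34, 5.71, 8.20, 2.42, 0.33)
  )
}

#' Simulate a choice panel directly from the utility model
#'
#' Inverts the discrete-choice model: for each individual a coefficient
#' vector is drawn from the mixing distribution; for each choice set, `J`
#' covariate vectors are drawn pre-standardized (mean 0, SD 0.5, i.e.
#' already on the 2-SD scale so the truth parameters are directly
#' comparable to fitted coefficients), utilities `z'b` receive independent
#' standard Gumbel noise, and the argmax alternative is chosen.
#' Alternatives are then reordered so the chosen one sits last (the
#' panel's construction convention); the pre-reorder position is kept in
#' `drawn_index`.
#'
#' @param truth A [truth_parameters()] object.
#' @param n_individuals Number of individuals (>= 1).
#' @param sets_per_individual Choice sets per individual: a scalar or a
#'   vector recycled to `n_individuals` (repeated choices are what
#'   identify the between-individual SDs in a panel).
#' @param J Alternatives per set (default 7).
#' @param covariate_sd SD of the simulated standardized covariates
#'   (default 0.5).
#' @param seed Integer seed.
#' @return A long-form choice panel tibble: `set_id`, `bird_id`,
#'   `alt_index` (1..J, chosen last), `drawn_index`, `chosen` (0/1) and
#'   one column per truth covariate. Attribute `individual_coefs` holds
#'   the per-individual coefficient draws.
#' @export
simulate_choice_sets <- function(truth, n_individuals,
                                 sets_per_individual = 1, J = 7,
                                 covariate_sd = 0.5, seed = 1L) {
  stopifnot(inherits(truth, "truth_parameters"), n_individuals >= 1,
            all(sets_per_individual >= 1), J >= 2)
  sets_per_individual <- rep_len(as.integer(sets_per_individual),
                                 n_individuals)
  set.seed(seed)
  K <- length(truth$covariates)
  b_ind <- matrix(rnorm(n_individuals * K), n_individuals, K)
  b_ind <- sweep(b_ind, 2, truth$s, "*")
  b_ind <- sweep(b_ind, 2, truth$beta, "+")
  colnames(b_ind) <- truth$covariates

  n_sets <- sum(sets_per_individual)
  n_alt <- n_sets * J
  Z <- matrix(rnorm(n_alt * K, 0, covariate_sd), n_alt, K)
  colnames(Z) <- truth$covariates
  ind_of_set <- rep(seq_len(n_individuals), times = sets_per_individual)
  ind_of_alt <- rep(ind_of_set, each = J)
  u <- rowSums(Z * b_ind[ind_of_alt, , drop = FALSE]) + rgumbel(n_alt)

  um <- matrix(u, nrow = J) # column = set
  chosen_pos <- max.col(t(um), ties.method = "first")

  set_of_alt <- rep(seq_len(n_sets), each = J)
  pos_in_set <- rep(seq_len(J), times = n_sets)
  # reorder within each set: non-chosen in original order, chosen last
  is_chosen <- pos_in_set == chosen_pos[set_of_alt]
  ord <- order(set_of_alt, is_chosen, pos_in_set)
  out <- tibble::tibble(
    set_id = set_of_alt[ord],
    bird_id = sprintf("bird_%03d", ind_of_alt[ord]),
    alt_index = rep(seq_len(J), times = n_sets),
    drawn_index = pos_in_set[ord],
    chosen = as.integer(is_chosen[ord])
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(Z[ord, , drop = FALSE]))
  attr(out, "individual_coefs") <- b_ind
  attr(out, "truth") <- truth
  out
}

#' Standard Gumbel random draws
#'
#' Location 0, scale 1 (the error distribution whose argmax yields the
#' conditional-logit choice probabilities).
#'
#' @param n Number of draws.
#' @return Numeric vector.
#' @export
rgumbel <- function(n) -log(-log(runif(n)))
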