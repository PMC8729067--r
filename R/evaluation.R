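#' Leave-one-out cross-validated percent correct
#'
#' For each choice set in turn, the model is refitted to the remaining
#' sets (warm-started from the full-data estimates) and the held-out set
#' is scored: the prediction is correct when its chosen (last)
#' alternative has strictly the highest utility at the refitted
#' population-mean coefficients. Individual-level coefficient deviations
#' are not used out of sample (the held-out individual's draw is
#' unobservable). Ties count as incorrect, with one principled exception:
#' under the equal-utility null model every alternative ties by
#' construction, so the prediction is a seeded uniform draw from the
#' model's own predictive distribution (expected percent correct `1/J`).
#' Folds whose refit fails outright (an error, or non-finite estimates)
#' are excluded from the mean and reported; a refit stopped by the
#' iteration cap is scored at its capped estimates (only ranking of
#' utilities matters out of sample, so e.g. perfectly separable folds,
#' where the MLE diverges, still score), with the optimizer's convergence
#' flag kept per fold.
#'
#' @param panel Long-form choice panel.
#' @param spec A [model_spec()].
#' @param n_draws,draw_type,seed Passed to [fit_choice_model()]; `seed`
#'   also drives the null model's uniform predictions.
#' @param maxit Per-fold BFGS iteration cap (warm starts keep refits
#'   short).
#' @param full_fit Optional pre-computed full-data `choice_fit` used for
#'   warm starts.
#' @return A `cv_result` list: `per_set` tibble (`set_id`, `correct`,
#'   `converged`), `pct_correct` (0-100), `n_used`, `n_failed`, and the
#'   model name.
#' @export
loo_cv <- function(panel, spec, n_draws = 500,
                   draw_type = c("halton", "pseudo"), seed = 1L,
                   maxit = 100, full_fit = NULL) {
  draw_type <- match.arg(draw_type)
  set_ids <- unique(panel$set_id)
  if (length(set_ids) < 2) stop("need at least 2 sets", call. = FALSE)

  if (spec$null) {
    sizes <- table(panel$set_id)
    J <- unique(as.integer(sizes))
    set.seed(seed)
    correct <- sample.int(J, length(set_ids), replace = TRUE) == J
    per_set <- tibble::tibble(set_id = set_ids, correct = correct,
                              converged = TRUE)
    res <- list(model = spec$name, per_set = per_set,
                pct_correct = 100 * mean(correct),
                n_used = length(set_ids), n_failed = 0L)
    class(res) <- "cv_result"
    return(res)
  }

  if (is.null(full_fit)) {
    full_fit <- fit_choice_model(panel, spec, n_draws = n_draws,
                                 draw_type = draw_type, seed = seed)
  }
  random_idx <- which(rep_len(spec$random, length(spec$covariates)))
  warm <- list(beta = unname(full_fit$coef),
               s = if (length(random_idx)) unname(full_fit$s[random_idx]))

  correct <- logical(length(set_ids))
  converged <- logical(length(set_ids))
  usable <- logical(length(set_ids))
  for (i in seq_along(set_ids)) {
    sid <- set_ids[i]
    train <- panel[panel$set_id != sid, , drop = FALSE]
    test <- panel[panel$set_id == sid, , drop = FALSE]
    refit <- tryCatch(
      fit_choice_model(train, spec, n_draws = n_draws,
                       draw_type = draw_type, seed = seed, start = warm,
                       maxit = maxit),
      error = function(e) NULL)
    usable[i] <- !is.null(refit) && all(is.finite(refit$coef)) &&
      is.finite(refit$loglik)
    if (!usable[i]) next
    converged[i] <- refit$converged
    u <- fit_utilities(refit, test)
    chosen_u <- u[test$chosen == 1]
    correct[i] <- chosen_u > max(u[test$chosen == 0])
  }
  per_set <- tibble::tibble(set_id = set_ids, correct = correct,
                            converged = converged, usable = usable)
  res <- list(model = spec$name, per_set = per_set,
              pct_correct = 100 * mean(per_set$correct[usable]),
              n_used = sum(usable), n_failed = sum(!usable))
  class(res) <- "cv_result"
  res
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: %.1f%% correct (%d folds used, %d failed)\n",
              x$model, x$pct_correct, x$n_used, x$n_failed))
  invisible(x)
}

#' Rank candidate models by BIC
#'
#' @param fits List of `choice_fit` objects.
#' @param cv Optional list of `cv_result` objects matched to `fits` by
#'   model name.
#' @return Tibble sorted by increasing BIC: `model`, `K`, `pct_correct`
#'   (if `cv` given), `BIC`, `delta_BIC` (0 for the top model) and
#'   `bic_weight` (normalized `exp(-delta/2)`, summing to 1).
#' @export
rank_models <- function(fits, cv = NULL) {
  stopifnot(length(fits) >= 1)
  tab <- purrr::map_dfr(fits, function(f)
    tibble::tibble(model = f$spec$name, K = f$K, BIC = f$bic))
  if (!is.null(cv)) {
    cvtab <- purrr::map_dfr(cv, function(x)
      tibble::tibble(model = x$model, pct_correct = x$pct_correct))
    tab <- dplyr::left_join(tab, cvtab, by = "model") |>
      dplyr::relocate("pct_correct", .after = "K")
  }
  tab <- dplyr::arrange(tab, .data$BIC) |>
    dplyr::mutate(delta_BIC = .data$BIC - .data$BIC[1])
  w <- exp(-tab$delta_BIC / 2)
  tab$bic_weight <- w / sum(w)
  tab
}

#' Variance inflation factors on the alternatives table
#'
#' For each covariate in the spec, `1 / (1 - R^2)` from the least-squares
#' regression of it on the other covariates, computed on the
#' (standardized) alternatives-level data. Perfect collinearity is
#' reported as `Inf` with a warning rather than an error.
#'
#' @param data Data frame of alternatives with the covariate columns.
#' @param covariates Covariates to check (>= 2).
#' @return Tibble `covariate`, `vif`.
#' @export
vif_choice <- function(data, covariates) {
  stopifnot(length(covariates) >= 2, all(covariates %in% names(data)),
            nrow(data) > length(covariates))
  vifs <- vapply(covariates, function(cv) {
    rhs <- setdiff(covariates, cv)
    fml <- stats::reformulate(rhs, response = cv)
    r2 <- summary(lm(fml, data = data))$r.squared
    if (r2 >= 1 - 1e-12) {
      warning("perfect collinearity for covariate '", cv, "'",
              call. = FALSE)
      Inf
    } else {
      1 / (1 - r2)
    }
  }, numeric(1))
  tibble::tibble(covariate = covariates, vif = unname(vifs))
}

#' Fisher-Pitman permutation test of a mean difference
#'
#' Permutation (randomization) test of the difference in group means
#' under random relabeling of the pooled observations. `Z` standardizes
#' the observed statistic against the permutation distribution's moments;
#' the two-sided p-value is the add-one-corrected proportion of permuted
#' `|statistic|` at least as large as observed.
#'
#' @param group_a,group_b Numeric vectors (non-empty).
#' @param n_perm Number of permutations (>= 100; default 1e5).
#' @param seed Seed.
#' @return List `statistic` (observed mean difference), `Z`, `p`,
#'   `n_perm`.
#' @export
fisher_pitman <- function(group_a, group_b, n_perm = 1e5, seed = 1L) {
  stopifnot(length(group_a) >= 1, length(group_b) >= 1)
  if (n_perm < 100) stop("n_perm must be at least 100", call. = FALSE)
  pooled <- c(group_a, group_b)
  na <- length(group_a)
  obs <- mean(group_a) - mean(group_b)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(pooled), na)
    mean(pooled[idx]) - mean(pooled[-idx])
  }, numeric(1))
  Z <- (obs - mean(perm)) / sd(perm)
  p <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
  list(statistic = obs, Z = Z, p = p, n_perm = n_perm)
}

#' Kolmogorov-Smirnov test of choice residuals against a Gumbel law
#'
#' Residuals are defined as the chosen indicator minus the predicted
#' conditional-logit probability of each alternative at the
#' population-mean coefficients (an explicit convention: the
#' discrete-choice literature defines no canonical residual). Within each
#' set they sum to zero because the probabilities sum to one. The
#' one-sample KS test compares them with a Gumbel distribution fitted by
#' moments.
#'
#' @param fit A `choice_fit`.
#' @param panel The panel the model was fitted to.
#' @return List `D`, `p`, `residual_median`, `residual_sd`, `residuals`.
#' @export
ks_gumbel_test <- function(fit, panel) {
  pd <- panel_data(panel, fit$spec$covariates, fit$spec$shifter)
  U <- matrix(drop(pd$Z %*% fit$coef[pd$covariates]), ncol = 1)
  M <- U
  dim(M) <- c(pd$J, pd$n_sets)
  P <- apply(M, 2, function(u) {
    e <- exp(u - max(u))
    e / sum(e)
  })
  panel_sorted <- dplyr::arrange(panel, .data$bird_id, .data$set_id,
                                 .data$alt_index)
  resid <- panel_sorted$chosen - as.vector(P)
  euler <- 0.5772156649015329
  bg <- sd(resid) * sqrt(6) / pi
  mu <- mean(resid) - euler * bg
  ks <- suppressWarnings(
    ks.test(resid, function(q) exp(-exp(-(q - mu) / bg))))
  list(D = unname(ks$statistic), p = ks$p.value,
       residual_median = stats::median(resid), residual_sd = sd(resid),
       residuals = resid)
}
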