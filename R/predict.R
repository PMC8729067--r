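#' Predicted response curves for a fitted choice model
#'
#' Sweeps one covariate over its observed raw-scale range while fixing the
#' others at their mean, 25th ("low") or 75th ("high") percentile, and
#' returns the predicted utility and exponential selection index at the
#' population-mean coefficients. Uncertainty bands are +/- 1 SE from a
#' parametric bootstrap of the coefficient means (multivariate normal on
#' the estimated covariance; seeded).
#'
#' @param fit A `choice_fit` whose spec contains the focal covariate and
#'   that stores the scaling constants used to standardize the panel.
#' @param focal Name of the covariate to sweep.
#' @param data Raw-scale covariate table (e.g. the record table before
#'   standardization) supplying the observed range and percentiles.
#' @param fix `"mean"`, `"p25"` or `"p75"` for the non-focal covariates.
#' @param n_grid Grid points (default 50).
#' @param n_boot Bootstrap resamples for the SE band (default 1000).
#' @param seed Seed for the bootstrap.
#' @return Tibble of class `response_curves`: `covariate`, `raw` (raw
#'   scale), `z` (standardized), `utility`, `utility_se`,
#'   `selection_index`, and `index_lo`/`index_hi` (+/- 1 SE on the index
#'   scale).
#' @export
predict_response_curves <- function(fit, focal, data,
                                    fix = c("mean", "p25", "p75"),
                                    n_grid = 50, n_boot = 1000, seed = 1L) {
  fix <- match.arg(fix)
  covs <- fit$spec$covariates
  if (!focal %in% covs) {
    stop("focal covariate '", focal, "' is not in the fitted model",
         call. = FALSE)
  }
  if (is.null(fit$scaling)) {
    stop("fit carries no scaling constants; refit with scaling =",
         call. = FALSE)
  }
  stopifnot(all(covs %in% names(data)))

  raw_grid <- seq(min(data[[focal]]), max(data[[focal]]),
                  length.out = n_grid)
  fix_fun <- switch(fix,
                    mean = mean,
                    p25 = function(x) quantile(x, 0.25, names = FALSE),
                    p75 = function(x) quantile(x, 0.75, names = FALSE))
  fixed_raw <- vapply(data[covs], fix_fun, numeric(1))

  newdata <- tibble::as_tibble(as.list(fixed_raw))[rep(1, n_grid), ]
  newdata[[focal]] <- raw_grid
  zz <- standardize_covariates(newdata, cols = covs,
                               scaling = fit$scaling)$data
  Zm <- as.matrix(zz[, covs, drop = FALSE])
  u <- drop(Zm %*% fit$coef[covs])

  u_se <- rep(NA_real_, n_grid)
  if (!is.null(fit$vcov)) {
    kb <- seq_along(fit$coef)
    vb <- fit$vcov[kb, kb, drop = FALSE]
    vb <- (vb + t(vb)) / 2
    set.seed(seed)
    bdraws <- MASS::mvrnorm(n_boot, mu = fit$coef, Sigma = vb)
    ub <- Zm %*% t(bdraws[, match(covs, names(fit$coef)), drop = FALSE])
    u_se <- apply(ub, 1, sd)
  }

  out <- tibble::tibble(
    covariate = focal, fix = fix, raw = raw_grid, z = zz[[focal]],
    utility = u, utility_se = u_se,
    selection_index = exp(u),
    index_lo = exp(u - u_se), index_hi = exp(u + u_se)
  )
  class(out) <- c("response_curves", class(out))
  out
}

#' Plot predicted response curves
#'
#' Utility (or selection index) against the focal covariate's raw scale
#' with a +/- 1 SE ribbon.
#'
#' @param object A `response_curves` tibble.
#' @param scale `"utility"` or `"index"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot response_curves
#' @export
autoplot.response_curves <- function(object, scale = c("utility", "index"),
                                     ...) {
  scale <- match.arg(scale)
  if (scale == "utility") {
    p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$raw,
                                              y = .data$utility)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$utility - .data$utility_se,
                                        ymax = .data$utility + .data$utility_se),
                           alpha = 0.25) +
      ggplot2::labs(y = "predicted utility")
  } else {
    p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$raw,
                                              y = .data$selection_index)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$index_lo,
                                        ymax = .data$index_hi),
                           alpha = 0.25) +
      ggplot2::labs(y = "selection index w(z)")
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = unique(object$covariate)) +
    ggplot2::theme_minimal()
}

#' Coefficient plot for a fitted choice model
#'
#' Point estimates with +/- 1 SE bars for coefficient means and
#' between-individual SDs.
#'
#' @param object A `choice_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot choice_fit
#' @export
autoplot.choice_fit <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$estimate - .data$std.error,
                                          xmax = .data$estimate + .data$std.error)) +
    ggplot2::facet_wrap(~type, scales = "free_x") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "estimate (2-SD covariate scale)", y = NULL)
}
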