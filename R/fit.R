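#' Fit a departure-choice model by maximum simulated likelihood
#'
#' Estimates a panel mixed (random-parameters) conditional logit:
#' coefficient means for every covariate in the spec, plus a
#' between-individual SD for each random coefficient. Optimization is
#' quasi-Newton (BFGS with numerical gradients) started from the
#' conditional-logit estimates with SDs initialized at 0.1; standard
#' errors come from the inverse numerical Hessian at the optimum. Each
#' individual receives its own block of the draw sequence (common across
#' that individual's sets, distinct between individuals -- the standard
#' estimation layout; see [make_draws()]). SDs are estimated
#' unconstrained (the likelihood is sign-invariant in them) and reported
#' as absolute values. With a fixed seed and draw settings the fit is
#' fully reproducible. Non-convergence is flagged in the result, never
#' silently dropped.
#'
#' The equal-utility null model is evaluated analytically: every
#' alternative has probability `1/J`, so the log-likelihood is
#' `n_sets * log(1/J)`; it is scored with `K = 2`.
#'
#' @param panel Long-form choice panel with the spec's covariate columns
#'   (standardized).
#' @param spec A [model_spec()].
#' @param n_draws Simulation draws per individual (default 500).
#' @param draw_type `"halton"` (default) or `"pseudo"`.
#' @param seed Seed for the draws.
#' @param start Optional named list `list(beta =, s =)` of warm-start
#'   values.
#' @param scaling Optional scaling tibble from [standardize_covariates()],
#'   stored for response-curve prediction.
#' @param maxit Maximum BFGS iterations.
#' @return A `choice_fit` object: estimates, SEs, covariance,
#'   log-likelihood, `K`, BIC, convergence flag and draw settings.
#'   Methods: [print()], [tidy()], [glance()].
#' @export
fit_choice_model <- function(panel, spec, n_draws = 500,
                             draw_type = c("halton", "pseudo"), seed = 1L,
                             start = NULL, scaling = NULL, maxit = 500) {
  draw_type <- match.arg(draw_type)
  stopifnot(inherits(spec, "model_spec"), nrow(panel) > 0)

  if (spec$null) {
    sizes <- table(panel$set_id)
    J <- unique(as.integer(sizes))
    stopifnot(length(J) == 1)
    n_sets <- length(sizes)
    ll <- n_sets * log(1 / J)
    fit <- list(spec = spec, coef = numeric(0), s = numeric(0),
                se = numeric(0), se_s = numeric(0), vcov = NULL,
                loglik = ll, K = spec$K, n_sets = n_sets,
                n_individuals = dplyr::n_distinct(panel$bird_id), J = J,
                bic = bic(ll, spec$K, n_sets), converged = TRUE,
                n_draws = n_draws, draw_type = draw_type, seed = seed,
                scaling = scaling, panel_covariates = NULL)
    class(fit) <- "choice_fit"
    return(fit)
  }

  pd <- panel_data(panel, spec$covariates, spec$shifter)
  Kb <- ncol(pd$Z)
  random_idx <- which(rep_len(spec$random, length(spec$covariates)))

  # conditional-logit starting values
  neg_cl <- function(b) -conditional_loglik(pd, b)
  neg_cl_gr <- function(b) -conditional_loglik_grad(pd, b)
  cl0 <- if (!is.null(start)) start$beta else {
    optim(rep(0, Kb), neg_cl, gr = neg_cl_gr, method = "BFGS",
          control = list(maxit = maxit, reltol = 1e-10))$par
  }

  if (length(random_idx) == 0) {
    opt <- optim(cl0, neg_cl, gr = neg_cl_gr, method = "BFGS",
                 hessian = TRUE,
                 control = list(maxit = maxit, reltol = 1e-10))
    est_beta <- opt$par
    est_s <- numeric(0)
    H <- opt$hessian
    ll <- -opt$value
    conv <- opt$convergence == 0
  } else {
    eta <- make_draws(length(random_idx), n_draws, draw_type, seed,
                      n_ind = pd$n_ind)
    obj <- msl_objective(pd, random_idx, eta)
    s0 <- if (!is.null(start) && !is.null(start$s)) {
      start$s
    } else {
      rep(0.1, length(random_idx))
    }
    split_par <- function(par) list(b = par[seq_len(Kb)],
                                    s = par[Kb + seq_along(random_idx)])
    neg_msl <- function(par) {
      p <- split_par(par)
      -obj$fn(p$b, p$s)
    }
    neg_msl_gr <- function(par) {
      p <- split_par(par)
      -obj$gr(p$b, p$s)
    }
    opt <- optim(c(cl0, s0), neg_msl, gr = neg_msl_gr, method = "BFGS",
                 hessian = TRUE,
                 control = list(maxit = maxit, reltol = 1e-9))
    est_beta <- opt$par[seq_len(Kb)]
    est_s <- abs(opt$par[Kb + seq_along(random_idx)])
    H <- opt$hessian
    ll <- -opt$value
    conv <- opt$convergence == 0
  }

  vc <- tryCatch(solve(H), error = function(e) NULL)
  se_all <- if (!is.null(vc)) {
    d <- diag(vc)
    ifelse(d > 0, sqrt(pmax(d, 0)), NA_real_)
  } else {
    rep(NA_real_, Kb + length(random_idx))
  }
  names(est_beta) <- pd$covariates
  s_full <- setNames(rep(0, length(spec$covariates)), spec$covariates)
  s_full[random_idx] <- est_s
  se_s <- setNames(rep(NA_real_, length(random_idx)),
                   spec$covariates[random_idx])
  if (length(random_idx) > 0) se_s[] <- se_all[Kb + seq_along(random_idx)]

  fit <- list(spec = spec,
              coef = est_beta,
              s = s_full,
              se = setNames(se_all[seq_len(Kb)], pd$covariates),
              se_s = se_s,
              vcov = vc,
              loglik = ll, K = spec$K, n_sets = pd$n_sets,
              n_individuals = pd$n_ind, J = pd$J,
              bic = bic(ll, spec$K, pd$n_sets),
              converged = conv,
              n_draws = n_draws, draw_type = draw_type, seed = seed,
              scaling = scaling,
              panel_covariates = pd$covariates)
  class(fit) <- "choice_fit"
  fit
}

#' @export
print.choice_fit <- function(x, ...) {
  cat("<choice_fit> ", x$spec$name, "\n", sep = "")
  cat(sprintf("  %d sets, %d individuals, J = %d; loglik = %.3f, K = %d, BIC = %.1f\n",
              x$n_sets, x$n_individuals, x$J, x$loglik, x$K, x$bic))
  if (!x$converged) cat("  ** optimizer did not report convergence **\n")
  if (length(x$coef) > 0) print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy a fitted departure-choice model
#'
#' @param x A `choice_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `type` (`"mean"` or `"sd"`), `estimate`,
#'   `std.error`.
#' @method tidy choice_fit
#' @export
tidy.choice_fit <- function(x, ...) {
  means <- tibble::tibble(term = names(x$coef), type = "mean",
                          estimate = unname(x$coef),
                          std.error = unname(x$se))
  rnd <- names(x$se_s)
  sds <- tibble::tibble(term = rnd, type = "sd",
                        estimate = unname(x$s[rnd]),
                        std.error = unname(x$se_s))
  dplyr::bind_rows(means, sds)
}

#' One-row summary of a fitted departure-choice model
#'
#' @param x A `choice_fit`.
#' @param ... Unused.
#' @return Tibble with `model`, `logLik`, `K`, `BIC`, `n_sets`,
#'   `n_individuals`, `n_draws`, `draw_type`, `converged`.
#' @method glance choice_fit
#' @export
glance.choice_fit <- function(x, ...) {
  tibble::tibble(model = x$spec$name, logLik = x$loglik, K = x$K,
                 BIC = x$bic, n_sets = x$n_sets,
                 n_individuals = x$n_individuals, n_draws = x$n_draws,
                 draw_type = x$draw_type, converged = x$converged)
}

# Utilities of every alternative at the population-mean coefficients.
fit_utilities <- function(fit, panel) {
  pd <- panel_data(panel, fit$spec$covariates, fit$spec$shifter)
  drop(pd$Z %*% fit$coef[pd$covariates])
}
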