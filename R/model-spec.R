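#' Define a candidate departure-choice model
#'
#' A model is a named subset of the ten covariates, each with either a
#' random (normally distributed across individuals; mean and SD both
#' estimated) or fixed coefficient, plus an optional individual-level
#' shifter (e.g. sex) entering the coefficient means, or the statistical
#' null model in which every alternative has identical utility.
#'
#' The parameter count `K` used for model ranking counts both the means
#' and the between-individual SDs; the null model is scored with `K = 2`
#' (the convention that reproduces its closed-form BIC on the published
#' model-selection table).
#'
#' @param name Model name.
#' @param covariates Character vector of covariate names (distinct).
#' @param random Logical vector (recycled): is each coefficient random?
#' @param shifter Optional name of an individual-level 0/1 column whose
#'   interaction with each covariate shifts the coefficient means.
#' @param null Logical: the equal-utility null model.
#' @return A `model_spec` object.
#' @export
model_spec <- function(name, covariates = character(), random = TRUE,
                       shifter = NULL, null = FALSE) {
  if (anyDuplicated(covariates)) stop("covariates must be distinct",
                                      call. = FALSE)
  random <- rep_len(as.logical(random), length(covariates))
  K <- if (null) 2L else {
    length(covariates) + sum(random) +
      (if (is.null(shifter)) 0L else length(covariates))
  }
  structure(list(name = name, covariates = covariates, random = random,
                 shifter = shifter, null = null, K = K),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", x$name, "\n", sep = "")
  if (x$null) {
    cat("  statistical null model (equal utilities), K = 2\n")
  } else {
    cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
    cat("  random:", paste(x$covariates[x$random], collapse = ", "), "\n")
    if (!is.null(x$shifter)) cat("  mean shifter:", x$shifter, "\n")
    cat("  K =", x$K, "\n")
  }
  invisible(x)
}

#' The candidate model set
#'
#' The full candidate set for the departure analysis: a null model, a
#' univariate model per covariate, a full model, daily-scale and
#' multi-day-scale bundles, and the winter-conditions model (temperature,
#' snow depth, frost days, snow days, ice cover). All coefficients are
#' random unless `random = FALSE`.
#'
#' @param random Logical, passed to each [model_spec()].
#' @param shifter Optional individual-level shifter column name.
#' @return Named list of `model_spec` objects.
#' @export
candidate_models <- function(random = TRUE, shifter = NULL) {
  uni <- lapply(covariate_names(), function(cv)
    model_spec(cv, cv, random = random, shifter = shifter))
  names(uni) <- covariate_names()
  c(
    list(
      null = model_spec("null", null = TRUE),
      full = model_spec("full", covariate_names(), random = random,
                        shifter = shifter),
      daily_scale = model_spec(
        "daily_scale",
        c("temp", "snow", "press_diff", "precip", "cloud", "tail", "head"),
        random = random, shifter = shifter),
      multi_day_scale = model_spec(
        "multi_day_scale", c("frost_days", "snow_days", "ice_cover"),
        random = random, shifter = shifter),
      winter_conditions = model_spec(
        "winter_conditions",
        c("temp", "snow", "frost_days", "snow_days", "ice_cover"),
        random = random, shifter = shifter)
    ),
    uni
  )
}
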