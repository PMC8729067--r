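#' Systematic utility of an alternative
#'
#' The linear predictor `z'b` of the random-utility model; the Gumbel
#' error enters only the probability derivation, not this value.
#'
#' @param z Covariate vector (or matrix with one row per alternative).
#' @param b Coefficient vector of matching length.
#' @return Numeric scalar (or vector for a matrix `z`).
#' @export
utility <- function(z, b) {
  if (is.matrix(z)) {
    if (ncol(z) != length(b)) stop("dimension mismatch", call. = FALSE)
    return(drop(z %*% b))
  }
  if (length(z) != length(b)) stop("dimension mismatch", call. = FALSE)
  sum(z * b)
}

#' Conditional-logit choice probabilities within a set
#'
#' Softmax of the alternatives' utilities, computed with max-subtraction
#' for numerical stability; the probabilities sum to one by construction.
#'
#' @param z Matrix of standardized covariates, one row per alternative.
#' @param beta Coefficient vector.
#' @return Numeric vector of probabilities, one per alternative.
#' @export
conditional_logit_probs <- function(z, beta) {
  if (!all(is.finite(z))) stop("non-finite covariates", call. = FALSE)
  if (nrow(z) < 2) stop("a choice set needs at least 2 alternatives",
                        call. = FALSE)
  u <- drop(z %*% beta)
  e <- exp(u - max(u))
  e / sum(e)
}

#' Exponential selection index
#'
#' `w(z) = exp(z'beta)`, the resource-selection-function form: within a
#' choice set the ratio of two alternatives' indices equals the ratio of
#' their conditional-logit probabilities.
#'
#' @param z Covariate vector or matrix (rows = alternatives).
#' @param beta Coefficient vector.
#' @param log Return the log index (overflow-safe).
#' @return Numeric scalar/vector.
#' @export
selection_index <- function(z, beta, log = FALSE) {
  u <- utility(z, beta)
  if (log) u else exp(u)
}

#' Bayesian Information Criterion for a choice model
#'
#' `-2 loglik + K log(n)`, with `n` the number of choice sets and `K`
#' counting both the coefficient means and the between-individual SDs.
#'
#' @param loglik Maximized log-likelihood.
#' @param K Parameter count.
#' @param n_sets Number of choice sets (>= 1).
#' @return Numeric scalar.
#' @export
bic <- function(loglik, K, n_sets) {
  stopifnot(n_sets >= 1)
  -2 * loglik + K * log(n_sets)
}

# ---- internal panel representation -----------------------------------------

# Validates a long-form panel and extracts the pieces the likelihood needs.
# Requires a constant set size J (guaranteed by build_choice_sets /
# simulate_choice_sets).
panel_data <- function(panel, covariates, shifter = NULL) {
  stopifnot(all(c("set_id", "bird_id", "alt_index", "chosen") %in%
                  names(panel)))
  missing_cov <- setdiff(covariates, names(panel))
  if (length(missing_cov) > 0) {
    stop("panel lacks covariate column(s): ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  panel <- dplyr::arrange(panel, .data$bird_id, .data$set_id,
                          .data$alt_index)
  sizes <- table(panel$set_id)
  J <- unique(as.integer(sizes))
  if (length(J) != 1) stop("all choice sets must have the same size",
                           call. = FALSE)
  n_sets <- length(sizes)
  Z <- as.matrix(panel[, covariates, drop = FALSE])
  if (!all(is.finite(Z))) stop("non-finite covariates", call. = FALSE)
  cov_names <- covariates
  if (!is.null(shifter)) {
    if (!shifter %in% names(panel)) {
      stop("panel lacks shifter column: ", shifter, call. = FALSE)
    }
    inter <- Z * panel[[shifter]]
    colnames(inter) <- paste0(covariates, ":", shifter)
    Z <- cbind(Z, inter)
    cov_names <- colnames(Z)
  }
  set_rows <- matrix(seq_len(nrow(panel)), nrow = J) # column = set
  chosen_pos <- apply(matrix(panel$chosen == 1, nrow = J), 2, which)
  if (!is.integer(chosen_pos) && !is.numeric(chosen_pos)) {
    stop("each set must have exactly one chosen alternative", call. = FALSE)
  }
  birds <- panel$bird_id[set_rows[1, ]]
  ind_of_set <- as.integer(factor(birds, levels = unique(birds)))
  list(Z = Z, J = J, n_sets = n_sets, n_alt = nrow(panel),
       chosen_pos = as.integer(chosen_pos),
       ind_of_set = ind_of_set,
       ind_of_alt = rep(ind_of_set, each = J),
       n_ind = max(ind_of_set),
       covariates = cov_names)
}

# ---- draws -----------------------------------------------------------------

# Radical-inverse (van der Corput) sequence in the given prime base.
radical_inverse <- function(idx, base) {
  r <- numeric(length(idx))
  f <- 1 / base
  i <- idx
  while (any(i > 0)) {
    r <- r + f * (i %% base)
    i <- i %/% base
    f <- f / base
  }
  r
}

halton_primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47)

#' Simulation draws for maximum simulated likelihood
#'
#' Standard-normal draws for the random coefficients, either quasi-random
#' (inverse-normal transformed Halton sequences, one prime base per
#' coefficient, first 50 points discarded, then centred on exactly zero
#' mean per coefficient) or pseudo-random. Draws are always common across
#' an individual's choice sets, as the panel likelihood requires. Two
#' layouts are available:
#'
#' * `n_ind = NULL` (shared): one draw set used by every individual,
#'   which makes the simulated log-likelihood exactly additive over
#'   individuals (a duplicated panel doubles it exactly).
#' * `n_ind` given (per-individual): each individual receives its own
#'   consecutive block of the sequence, the standard estimation layout --
#'   per-individual integration errors then partially average out across
#'   individuals.
#'
#' @param n_coef Number of random coefficients.
#' @param n_draws Draws per individual (default 500).
#' @param type `"halton"` or `"pseudo"`.
#' @param seed Seed (used by the pseudo-random type).
#' @param n_ind Number of individuals for the per-individual layout, or
#'   `NULL` for the shared layout.
#' @return Matrix `c(n_coef, n_draws)` (shared) or array
#'   `c(n_ind, n_coef, n_draws)` (per-individual).
#' @export
make_draws <- function(n_coef, n_draws = 500, type = c("halton", "pseudo"),
                       seed = 1L, n_ind = NULL) {
  type <- match.arg(type)
  stopifnot(n_draws >= 1, n_coef >= 1)
  n_blocks <- if (is.null(n_ind)) 1L else as.integer(n_ind)
  n_tot <- n_blocks * n_draws
  if (type == "halton") {
    if (n_coef > length(halton_primes)) {
      stop("too many random coefficients for Halton draws", call. = FALSE)
    }
    idx <- 50 + seq_len(n_tot)
    eta <- vapply(seq_len(n_coef), function(k)
      qnorm(radical_inverse(idx, halton_primes[k])), numeric(n_tot))
    if (n_tot > 1) {
      # centre each coefficient's draws on exactly zero; rescaling the SD
      # is deliberately avoided (it degrades quadrature-level accuracy)
      eta <- sweep(eta, 2, colMeans(eta))
    }
  } else {
    set.seed(seed)
    eta <- matrix(rnorm(n_tot * n_coef), n_tot, n_coef)
  }
  if (is.null(n_ind)) {
    t(eta)
  } else {
    # draw index varies fastest within an individual's block
    aperm(array(eta, dim = c(n_draws, n_blocks, n_coef)), c(2, 3, 1))
  }
}

# ---- log-likelihoods -------------------------------------------------------

# Per-set log probability of the chosen alternative given a utility vector
# for all alternatives; U is an (n_alt x R) matrix (R = 1 for conditional
# logit). Returns an (n_sets x R) matrix.
set_log_probs <- function(U, pd) {
  R <- ncol(U)
  M <- U
  dim(M) <- c(pd$J, pd$n_sets * R)
  m <- M[1, ]
  for (j in 2:pd$J) m <- pmax(m, M[j, ])
  lse <- m + log(colSums(exp(sweep(M, 2, m))))
  chosen <- M[cbind(rep(pd$chosen_pos, times = R),
                    seq_len(pd$n_sets * R))]
  matrix(chosen - lse, nrow = pd$n_sets)
}

conditional_loglik <- function(pd, beta) {
  U <- matrix(drop(pd$Z %*% beta), ncol = 1)
  sum(set_log_probs(U, pd))
}

# Softmax matrix (J x n_sets*R) for a utility matrix U (n_alt x R).
set_probs <- function(U, pd) {
  R <- ncol(U)
  M <- U
  dim(M) <- c(pd$J, pd$n_sets * R)
  m <- M[1, ]
  for (j in 2:pd$J) m <- pmax(m, M[j, ])
  E <- exp(sweep(M, 2, m))
  sweep(E, 2, colSums(E), "/")
}

# Analytic gradient of the conditional-logit loglik.
conditional_loglik_grad <- function(pd, beta) {
  U <- matrix(drop(pd$Z %*% beta), ncol = 1)
  P <- set_probs(U, pd) # J x n_sets
  chosen_rows <- (seq_len(pd$n_sets) - 1) * pd$J + pd$chosen_pos
  Zc <- pd$Z[chosen_rows, , drop = FALSE] # n_sets x K
  # expected covariate under the model, per set
  EZ <- rowsum(as.vector(P) * pd$Z, rep(seq_len(pd$n_sets), each = pd$J))
  colSums(Zc - EZ)
}

# Factory: precomputes the per-draw random-utility components so repeated
# likelihood evaluations during optimization only rescale them. Returns
# the simulated loglik and its analytic gradient in (beta, s). `eta` is
# either a shared (n_coef x R) matrix or a per-individual
# (n_ind x n_coef x R) array from make_draws().
msl_objective <- function(pd, random_idx, eta) {
  per_ind <- length(dim(eta)) == 3
  R <- if (per_ind) dim(eta)[3] else ncol(eta)
  A <- lapply(seq_along(random_idx), function(kk) {
    if (per_ind) {
      pd$Z[, random_idx[kk]] * matrix(eta[pd$ind_of_alt, kk, ],
                                      nrow = pd$n_alt)
    } else {
      outer(pd$Z[, random_idx[kk]], eta[kk, ])
    }
  })
  eta_by_set <- function(kk) {
    if (per_ind) {
      matrix(eta[pd$ind_of_set, kk, ], nrow = pd$n_sets)
    } else {
      matrix(eta[kk, ], pd$n_sets, R, byrow = TRUE)
    }
  }
  set_of_col <- rep(seq_len(pd$n_sets), times = R)
  chosen_flat <- cbind(rep(pd$chosen_pos, times = R),
                       seq_len(pd$n_sets * R))

  eval_parts <- function(beta, s) {
    U <- matrix(drop(pd$Z %*% beta), pd$n_alt, R)
    for (kk in seq_along(A)) U <- U + s[kk] * A[[kk]]
    P <- set_probs(U, pd) # J x (n_sets*R)
    lp <- matrix(log(P[chosen_flat]), nrow = pd$n_sets)
    Lir <- rowsum(lp, pd$ind_of_set) # n_ind x R
    mi <- apply(Lir, 1, max)
    list(P = P, Lir = Lir, mi = mi,
         ll = sum(mi + log(rowMeans(exp(Lir - mi)))))
  }

  fn <- function(beta, s) eval_parts(beta, s)$ll

  gr <- function(beta, s) {
    parts <- eval_parts(beta, s)
    # per-individual softmax weights over draws
    Ew <- exp(parts$Lir - parts$mi)
    W <- Ew / rowSums(Ew) # n_ind x R
    V <- W[pd$ind_of_set, , drop = FALSE] # n_sets x R
    K <- ncol(pd$Z)
    gb <- numeric(K)
    gs <- numeric(length(random_idx))
    p_vec <- as.vector(parts$P)
    seq_nr <- seq_len(pd$n_sets * R)
    for (k in seq_len(K)) {
      zk <- pd$Z[, k]
      # chosen-minus-expected covariate, per set and draw (column-major
      # recycling of the J x n_sets block across draws)
      Ek <- matrix(colSums(matrix(p_vec * zk, nrow = pd$J)),
                   nrow = pd$n_sets)
      Gk <- matrix(zk[(set_of_col - 1) * pd$J + rep(pd$chosen_pos, R)],
                   nrow = pd$n_sets) - Ek
      gb[k] <- sum(V * Gk)
      kk <- match(k, random_idx)
      if (!is.na(kk)) {
        gs[kk] <- sum(V * Gk * eta_by_set(kk))
      }
    }
    c(gb, gs)
  }

  list(fn = fn, gr = gr)
}

#' Panel simulated log-likelihood of a mixed logit
#'
#' For each individual and draw, the coefficient vector is
#' `beta + s * eta` (draws common across that individual's sets); the
#' simulated likelihood of an individual is the average over draws of the
#' product over its sets of the chosen alternative's conditional-logit
#' probability, and the panel log-likelihood sums the log simulated
#' likelihoods. With `s = 0` this reduces exactly to the conditional-logit
#' log-likelihood. Deterministic given the draw settings.
#'
#' @param panel Long-form choice panel.
#' @param covariates Covariate columns entering the utility.
#' @param beta Mean coefficients (one per covariate).
#' @param s Between-individual SDs; either length-matched to `beta` (zeros
#'   mark fixed coefficients) or a named subset.
#' @param n_draws,draw_type,seed Draw settings (see [make_draws()]).
#' @param random Indices (or names) of the covariates treated as random.
#'   Defaults to those with nonzero `s`; passing coefficients with
#'   `s = 0` explicitly runs them through the full simulation machinery,
#'   where the mixed log-likelihood collapses to the conditional-logit
#'   value exactly.
#' @return Scalar log-likelihood.
#' @export
panel_simulated_loglik <- function(panel, covariates, beta, s,
                                   n_draws = 500,
                                   draw_type = c("halton", "pseudo"),
                                   seed = 1L, random = NULL) {
  draw_type <- match.arg(draw_type)
  pd <- panel_data(panel, covariates)
  if (any(tabulate(pd$ind_of_set, pd$n_ind) == 0)) {
    stop("every individual must contribute at least one set", call. = FALSE)
  }
  s <- rep_len(s, length(beta))
  random_idx <- if (is.null(random)) {
    which(s != 0)
  } else if (is.character(random)) {
    match(random, covariates)
  } else {
    as.integer(random)
  }
  if (length(random_idx) == 0) return(conditional_loglik(pd, beta))
  eta <- make_draws(length(random_idx), n_draws, draw_type, seed)
  msl_objective(pd, random_idx, eta)$fn(beta, s[random_idx])
}
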