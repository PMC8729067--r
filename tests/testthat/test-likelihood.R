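test_that("utility and selection index follow their algebra", {
  expect_equal(utility(c(0, 0), c(3, -1)), 0)
  expect_equal(utility(c(1, 2), c(0, 0)), 0)
  expect_equal(utility(c(1, 2), c(3, -1)), 1)
  expect_error(utility(c(1, 2), 1), "dimension mismatch")

  expect_equal(selection_index(c(1, 2), c(0, 0)), 1)
  expect_equal(selection_index(log(2), 1), 2)
  # within-set ratio identity: w(z1)/w(z2) == P(z1)/P(z2)
  set.seed(2)
  z <- matrix(rnorm(14), 7, 2)
  beta <- c(1.3, -0.7)
  p <- conditional_logit_probs(z, beta)
  w <- selection_index(z, beta)
  expect_equal(w[1] / w[2], p[1] / p[2], tolerance = 1e-12)
})

test_that("conditional-logit probabilities are a stable softmax", {
  z0 <- matrix(0, 7, 1)
  expect_equal(conditional_logit_probs(z0, 0), rep(1 / 7, 7))
  # closed form: one covariate, last alternative at ln 6, beta = 1
  z <- matrix(c(rep(0, 6), log(6)), 7, 1)
  p <- conditional_logit_probs(z, 1)
  expect_equal(p[7], 0.5)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # extreme utilities do not overflow
  zx <- matrix(c(-1000, 1000, 0), 3, 1)
  px <- conditional_logit_probs(zx, 1)
  expect_true(all(is.finite(px)))
  expect_equal(sum(px), 1, tolerance = 1e-12)
  expect_error(conditional_logit_probs(matrix(NA_real_, 7, 1), 1),
               "non-finite")
})

test_that("Halton draws reproduce radical-inverse values and normal moments", {
  # hand-computed radical inverses: base 2 of 1..4 = 1/2, 1/4, 3/4, 1/8;
  # base 3 of 1..4 = 1/3, 2/3, 1/9, 4/9
  expect_equal(migchoice:::radical_inverse(1:4, 2),
               c(1 / 2, 1 / 4, 3 / 4, 1 / 8))
  expect_equal(migchoice:::radical_inverse(1:4, 3),
               c(1 / 3, 2 / 3, 1 / 9, 4 / 9))
  eta <- make_draws(2, n_draws = 500, type = "halton")
  expect_equal(dim(eta), c(2, 500))
  expect_lt(max(abs(rowMeans(eta))), 0.05)
  expect_equal(apply(eta, 1, sd), c(1, 1), tolerance = 0.02)
  # pseudo draws are seed-reproducible
  e1 <- make_draws(2, 50, type = "pseudo", seed = 3)
  e2 <- make_draws(2, 50, type = "pseudo", seed = 3)
  expect_identical(e1, e2)
})

test_that("simulated panel loglik reduces to closed forms", {
  truth <- truth_parameters(c("temp", "snow"), beta = c(1, -1),
                            s = c(0.8, 0))
  pan <- simulate_choice_sets(truth, n_individuals = 30,
                              sets_per_individual = 2, seed = 10)
  # null model: all utilities equal
  expect_equal(panel_simulated_loglik(pan, c("temp", "snow"),
                                      beta = c(0, 0), s = 0),
               60 * log(1 / 7))
  # s = 0: exact conditional-logit identity (not a tolerance)
  beta <- c(0.9, -1.2)
  ll_s0 <- panel_simulated_loglik(pan, c("temp", "snow"), beta, s = 0,
                                  n_draws = 17)
  pd <- migchoice:::panel_data(pan, c("temp", "snow"))
  expect_identical(ll_s0, migchoice:::conditional_loglik(pd, beta))
  # duplicated panel doubles the loglik exactly
  pan2 <- pan
  pan2$bird_id <- paste0(pan2$bird_id, "_copy")
  pan2$set_id <- pan2$set_id + max(pan$set_id)
  ll1 <- panel_simulated_loglik(pan, c("temp", "snow"), beta,
                                s = c(0.5, 0.2), n_draws = 50)
  lld <- panel_simulated_loglik(dplyr::bind_rows(pan, pan2),
                                c("temp", "snow"), beta,
                                s = c(0.5, 0.2), n_draws = 50)
  expect_equal(lld, 2 * ll1, tolerance = 1e-12)
})

test_that("simulated loglik converges to Gauss-Hermite quadrature", {
  skip_if_not_installed("pracma")
  truth <- truth_parameters("temp", beta = 1.5, s = 1.2)
  pan <- simulate_choice_sets(truth, n_individuals = 25,
                              sets_per_individual = 2, seed = 19)
  pd <- migchoice:::panel_data(pan, "temp")
  gh <- pracma::gaussHermite(64)
  quad <- 0
  for (a in seq_len(pd$n_ind)) {
    sets <- which(pd$ind_of_set == a)
    val <- 0
    for (q in seq_along(gh$x)) {
      b <- 1.5 + 1.2 * sqrt(2) * gh$x[q]
      lp <- 0
      for (sid in sets) {
        rows <- (sid - 1) * pd$J + seq_len(pd$J)
        u <- pd$Z[rows, 1] * b
        lp <- lp + u[pd$chosen_pos[sid]] -
          (max(u) + log(sum(exp(u - max(u)))))
      }
      val <- val + gh$w[q] / sqrt(pi) * exp(lp)
    }
    quad <- quad + log(val)
  }
  ll <- panel_simulated_loglik(pan, "temp", beta = 1.5, s = 1.2,
                               n_draws = 1e4)
  expect_lt(abs(ll - quad), 1e-3)
})

test_that("BIC follows -2 loglik + K log(n_sets)", {
  expect_equal(bic(0, 0, 10), 0)
  expect_equal(bic(73 * log(1 / 7), 2, 73), 292.68, tolerance = 0.05)
  expect_equal(bic(-100, 3, 50), 200 + 3 * log(50))
})
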