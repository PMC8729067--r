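test_that("null-model LOO-CV converges to 1/7", {
  truth <- truth_parameters("temp", beta = 0, s = 0)
  pan <- simulate_choice_sets(truth, n_individuals = 700, seed = 3)
  cv <- loo_cv(pan, model_spec("null", null = TRUE), seed = 17)
  p_hat <- cv$pct_correct / 100
  se <- sqrt((1 / 7) * (6 / 7) / 700)
  expect_lt(abs(p_hat - 1 / 7), 1.96 * se)
  expect_equal(cv$n_used, 700)
})

test_that("a separable signal is predicted perfectly out of sample", {
  # chosen alternative always carries the largest covariate value
  truth <- truth_parameters("temp", beta = 400, s = 0)
  pan <- simulate_choice_sets(truth, n_individuals = 30, seed = 21)
  cv <- loo_cv(pan, model_spec("m", "temp", random = FALSE), maxit = 50)
  expect_equal(cv$pct_correct, 100)
})

test_that("model ranking orders by BIC with normalized weights", {
  mk_fit <- function(name, bicv) {
    structure(list(spec = model_spec(name, null = TRUE), K = 2L,
                   bic = bicv), class = "choice_fit")
  }
  one <- rank_models(list(mk_fit("a", 100)))
  expect_equal(one$delta_BIC, 0)
  expect_equal(one$bic_weight, 1)

  two <- rank_models(list(mk_fit("a", 100), mk_fit("b", 100)))
  expect_equal(two$bic_weight, c(0.5, 0.5))

  # printed-table spacing: delta of 19.5 gives weight ratio exp(-9.75)
  pair <- rank_models(list(mk_fit("top", 223.3), mk_fit("second", 242.8)))
  expect_equal(pair$delta_BIC, c(0, 19.5))
  expect_equal(pair$bic_weight[2] / pair$bic_weight[1], exp(-9.75),
               tolerance = 1e-12)
  expect_equal(sum(pair$bic_weight), 1, tolerance = 1e-12)

  shuffled <- rank_models(list(mk_fit("b", 300), mk_fit("a", 200)))
  expect_equal(shuffled$model, c("a", "b"))
})

test_that("variance inflation factors match their closed form", {
  set.seed(5)
  n <- 400
  # orthogonalized pair: VIF 1
  x1 <- rnorm(n)
  x2 <- residuals(lm(rnorm(n) ~ x1))
  d <- tibble::tibble(a = x1, b = x2)
  v <- vif_choice(d, c("a", "b"))
  expect_equal(v$vif, c(1, 1), tolerance = 0.02)
  # x2 = x1 + noise tuned to R^2 = 0.75 -> VIF ~ 4
  x3 <- x1 + rnorm(n, 0, sd = sqrt(var(x1) / 3))
  d2 <- tibble::tibble(a = x1, b = x3)
  v2 <- vif_choice(d2, c("a", "b"))
  expect_equal(v2$vif, c(4, 4), tolerance = 0.6)
  # VIF is invariant to affine rescaling
  d3 <- dplyr::mutate(d2, a = 10 * a - 3)
  expect_equal(vif_choice(d3, c("a", "b"))$vif, v2$vif, tolerance = 1e-8)
  # duplicated covariate: infinite with a warning
  d4 <- tibble::tibble(a = x1, b = x1)
  w <- testthat::capture_warnings(v4 <- vif_choice(d4, c("a", "b")))
  expect_true(sum(grepl("collinearity", w)) == 2)
  expect_true(all(is.infinite(v4$vif)))
})

test_that("Fisher-Pitman permutation test behaves across regimes", {
  set.seed(7)
  x <- rnorm(20)
  same <- fisher_pitman(x, x, n_perm = 2000, seed = 1)
  expect_gt(same$p, 0.9)
  # two large samples shifted by 5 SDs
  a <- rnorm(200); b <- rnorm(200) + 5
  far <- fisher_pitman(a, b, n_perm = 1e4, seed = 2)
  expect_lte(far$p, 1e-3)
  expect_lt(far$Z, -10)
  expect_error(fisher_pitman(a, b, n_perm = 50), "at least 100")
})

test_that("permutation p matches exhaustive enumeration on 4+4 groups", {
  a <- c(1.2, 0.4, -0.3, 2.1)
  b <- c(-0.5, 0.9, -1.4, 0.2)
  pooled <- c(a, b)
  combs <- utils::combn(8, 4)
  exact_stats <- apply(combs, 2, function(i)
    mean(pooled[i]) - mean(pooled[-i]))
  obs <- mean(a) - mean(b)
  p_exact <- mean(abs(exact_stats) >= abs(obs) - 1e-12)
  mc <- fisher_pitman(a, b, n_perm = 1e5, seed = 9)
  expect_lt(abs(mc$p - p_exact), 0.01)
})

test_that("permutation p-values are not anti-conservative under the null", {
  set.seed(11)
  ps <- replicate(300, {
    x <- rnorm(8); y <- rnorm(8)
    fisher_pitman(x, y, n_perm = 199, seed = sample.int(1e6, 1))$p
  })
  expect_gte(mean(ps <= 0.05), 0) # sanity floor
  expect_lte(mean(ps <= 0.05), 0.08) # super-uniform or close
})

test_that("choice residuals sum to zero per set and the KS test runs", {
  truth <- truth_parameters("temp", beta = 1.5, s = 0)
  pan <- simulate_choice_sets(truth, n_individuals = 60, seed = 23)
  fit <- fit_choice_model(pan, model_spec("m", "temp", random = FALSE))
  ks <- ks_gumbel_test(fit, pan)
  rmat <- matrix(ks$residuals, nrow = 7)
  expect_true(all(abs(colSums(rmat)) < 1e-10))
  expect_true(ks$D >= 0 && ks$D <= 1)
  expect_true(ks$p >= 0 && ks$p <= 1)
  # draws from the reference Gumbel itself are not rejected systematically
  set.seed(2)
  g <- -log(-log(runif(500)))
  euler <- 0.5772156649015329
  bg <- sd(g) * sqrt(6) / pi
  mu <- mean(g) - euler * bg
  ks2 <- suppressWarnings(
    stats::ks.test(g, function(q) exp(-exp(-(q - mu) / bg))))
  expect_gt(ks2$p.value, 0.01)
})
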