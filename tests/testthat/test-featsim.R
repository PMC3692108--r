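test_that("independent features fit a near-diagonal target and identity Cholesky", {
  set.seed(501)
  x <- make_correlated_features(2000, diag(2))
  cm <- fit_correlation_model(x, mode = "full")
  expect_lt(abs(cm$rho[1, 2]), 3 / sqrt(2000))
  # identity target -> identity factor
  cm$r <- diag(2)
  expect_equal(chol(cm$r), diag(2))
  expect_error(fit_correlation_model(cbind(x, k = rep(1, 2000))),
               "constant")
})

test_that("a duplicated feature is repaired to a factorizable comonotone target", {
  set.seed(502)
  x <- make_correlated_features(500, diag(1), feature_names = "a")
  x <- cbind(x, b = x[, 1])
  cm <- suppressMessages(fit_correlation_model(x, mode = "full"))
  expect_equal(cm$rho[1, 2], 1)
  L <- cm$chol[[1]]
  expect_equal(L %*% t(L), cm$r, tolerance = 1e-4)
  sim <- simulate_features(cm, 500)
  expect_gt(cor(sim[, 1], sim[, 2], method = "spearman"), 0.99)
})

test_that("pairwise and triplet copulas recover their target Spearman correlations", {
  set.seed(503)
  rho_pair <- 0.8
  R <- diag(5)
  R[1, 2] <- R[2, 1] <- rho_pair
  R[3, 4] <- R[4, 3] <- 0.5
  R[3, 5] <- R[5, 3] <- 0.4
  R[4, 5] <- R[5, 4] <- 0.45
  marg <- list(marginal_spec("normal"), marginal_spec("exponential"),
               marginal_spec("normal_mixture"), marginal_spec("uniform"),
               marginal_spec("normal", mean = 3, sd = 0.5))
  orig <- make_correlated_features(4000, R, marg)
  cm <- fit_correlation_model(orig, mode = "full")
  sim <- simulate_features(cm, 4000)
  rho_o <- cor(orig, method = "spearman")
  rho_s <- cor(sim, method = "spearman")
  expect_lt(max(abs(rho_s - rho_o)), 0.07)
  expect_lt(abs(rho_s[1, 2] - 0.8), 0.05)
  # marginal preservation under the copula: KS bounds as in 1D mode
  for (j in 1:5) expect_lt(ks_distance(orig[, j], sim[, j]), 0.08)
})

test_that("auto-grouping keeps declared group structure and between-group independence", {
  set.seed(504)
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- 0.9
  R[3, 4] <- R[4, 3] <- 0.6
  orig <- make_correlated_features(3000, R)
  cm <- fit_correlation_model(orig, mode = "pairwise_2d")
  expect_true(all(vapply(cm$groups, length, 0L) <= 2))
  expect_setequal(lapply(cm$groups, sort), list(c(1L, 2L), c(3L, 4L)))
  sim <- simulate_features(cm, 3000)
  rho_s <- cor(sim, method = "spearman")
  rho_o <- cor(orig, method = "spearman")
  expect_lt(abs(rho_s[1, 2] - rho_o[1, 2]), 0.05)
  expect_lt(abs(rho_s[1, 3]), 3 / sqrt(3000))  # between-group independence
  # triplet with identity correlation: identity copula
  cm3 <- fit_correlation_model(make_correlated_features(3000, diag(3)),
                               mode = "triplet_3d")
  sim3 <- simulate_features(cm3, 3000)
  r3 <- cor(sim3, method = "spearman")
  expect_true(all(abs(r3[upper.tri(r3)]) < 3 / sqrt(3000)))
})

test_that("independent_1d mode preserves marginals without inducing dependence", {
  set.seed(505)
  marg <- list(marginal_spec("exponential", rate = 0.5),
               marginal_spec("normal_mixture", means = c(-3, 3)))
  orig <- make_correlated_features(5000, diag(2), marg)
  cm <- fit_correlation_model(orig, mode = "independent_1d")
  sim <- simulate_features(cm, 5000)
  for (j in 1:2) expect_lt(ks_distance(orig[, j], sim[, j]), 0.08)
  # determinism
  set.seed(9); a <- simulate_features(cm, 20)
  set.seed(9); b <- simulate_features(cm, 20)
  expect_identical(a, b)
})
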