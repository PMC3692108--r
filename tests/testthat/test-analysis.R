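test_that("spearman_matrix is monotone-invariant and flags constant columns", {
  set.seed(701)
  x <- rnorm(50)
  m <- cbind(a = x, b = exp(x), c = -x)
  rho <- spearman_matrix(m)
  expect_equal(rho[1, 2], 1)
  expect_equal(rho[1, 3], -1)
  expect_true(isSymmetric(rho))
  # tied toy set against the direct rank formula
  toy <- cbind(u = c(1, 2, 2, 4), v = c(10, 30, 20, 40))
  expect_equal(spearman_matrix(toy)[1, 2],
               cor(rank(toy[, 1]), rank(toy[, 2])))
  expect_warning(rc <- spearman_matrix(cbind(m, k = rep(1, 50))),
                 "constant")
  expect_true(is.na(rc["a", "k"]))
  expect_equal(diag(rc), rep(1, 4), ignore_attr = TRUE)
})

test_that("normality detection flags Gaussian data and rejects gross non-normality", {
  set.seed(702)
  flags <- replicate(10, {
    x <- cbind(f1 = rnorm(1000))
    normality_tests(x)$univariate$normal
  })
  expect_gte(mean(flags), 0.9)
  xe <- cbind(f1 = rexp(5000))
  expect_false(normality_tests(xe)$univariate$normal)

  # Mardia calibration on a correlated bivariate normal
  flags2 <- replicate(10, {
    y <- make_correlated_features(2000, matrix(c(1, .5, .5, 1), 2))
    normality_tests(y, groups = list(c(1, 2)))$multivariate$normal
  })
  expect_gte(mean(flags2), 0.9)
  y <- make_correlated_features(2000, diag(2),
                                list(marginal_spec("exponential"),
                                     marginal_spec("exponential")))
  expect_false(normality_tests(y, groups = list(c(1, 2)))$multivariate$normal)
  expect_error(normality_tests(y, groups = list(1:4)), "size 2 or 3")
})

test_that("compare_sets reports identity, divergence and preserved correlations", {
  set.seed(703)
  x <- make_correlated_features(500, matrix(c(1, .6, .6, 1), 2))
  same <- compare_sets(x, x)
  expect_equal(unname(same$ks), c(0, 0))
  expect_equal(max(same$spearman_abs_diff), 0)
  disjoint <- x + 1000
  expect_equal(unname(compare_sets(x, disjoint)$ks), c(1, 1))
  # simulated-from-model comparison stays inside the copula fidelity bound
  cm <- fit_correlation_model(x, mode = "full")
  sim <- simulate_features(cm, 4000)
  cmp <- compare_sets(x, sim)
  expect_lt(max(cmp$spearman_abs_diff), 0.07)
  expect_error(compare_sets(x, matrix(1:4, 2,
                                      dimnames = list(NULL, c("z", "w")))),
               "names differ")
})

test_that("all three classifier kinds separate well-separated clusters", {
  tr <- make_two_class_features(200, p = 2, shift = 6, rho = 0, seed = 704)
  te <- make_two_class_features(200, p = 2, shift = 6, rho = 0, seed = 705)
  for (kind in c("gaussian_naive_bayes", "pnn_gaussian",
                 "pnn_exponential")) {
    m <- train_classifier(tr$features, tr$labels, kind)
    met <- classification_metrics(predict(m, te$features), te$labels)
    expect_gte(met[["accuracy"]], 0.95)
  }
  expect_error(train_classifier(tr$features, rep(1, 400), "pnn_gaussian"),
               "both classes")
  # sigma -> Inf collapses PNN predictions to the majority prior
  unb <- list(features = tr$features,
              labels = c(rep(0L, 150), rep(1L, 250)))
  m <- train_classifier(unb$features, unb$labels, "pnn_gaussian",
                        sigma = 1e9)
  expect_true(all(predict(m, te$features) == 1L))
})

test_that("metrics agree with confusion-count oracles and hit the extremes", {
  y <- c(rep(1, 10), rep(0, 10))
  expect_equal(unname(classification_metrics(y, y)), c(1, 1, 1))
  expect_equal(classification_metrics(1 - y, y)[["mcc"]], -1)
  expect_equal(unname(classification_metrics(
    c(rep(1, 8), rep(1, 2), rep(0, 2), rep(0, 8)),
    c(rep(1, 8), rep(0, 2), rep(1, 2), rep(0, 8)))),
    c(0.8, 0.8, 0.6))
  set.seed(706)
  for (i in 1:1000) {
    n <- sample(5:30, 1)
    pred <- sample(0:1, n, TRUE)
    act <- sample(0:1, n, TRUE)
    m <- classification_metrics(pred, act)
    expect_equal(as.numeric(m), oracle_metrics(pred, act), tolerance = 1e-12)
    expect_true(m[["mcc"]] >= -1 && m[["mcc"]] <= 1)
    expect_true(m[["f_score"]] >= 0 && m[["f_score"]] <= 1)
  }
  expect_error(classification_metrics(c(0, 1), c(0, 1, 1)), "equal length")
})

test_that("feature-subset search enumerates subsets and finds the informative feature", {
  set.seed(707)
  n <- 120
  informative <- c(rnorm(n / 2, 0), rnorm(n / 2, 3))
  tr <- cbind(sig = informative, n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  labels <- rep(0:1, each = n / 2)
  te_sig <- c(rnorm(n / 2, 0), rnorm(n / 2, 3))
  te <- cbind(sig = te_sig, n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  tab <- feature_combination_search(tr, te, labels, labels)
  expect_equal(nrow(tab), 15)
  expect_match(tab$features[1], "sig")
  one <- feature_combination_search(tr[, 1, drop = FALSE],
                                    te[, 1, drop = FALSE], labels, labels)
  expect_equal(nrow(one), 1)
})
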