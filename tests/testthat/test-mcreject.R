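test_that("quantile bounds follow the interpolated-quantile formula", {
  x <- matrix(1:100, ncol = 1, dimnames = list(NULL, "a"))
  b0 <- quantile_bounds(x, 0)
  expect_equal(unname(b0[, 1]), c(1, 100))
  b <- quantile_bounds(x, 0.05)
  # type-7 interpolation oracle: 1 + 0.05 * 99 and 1 + 0.95 * 99
  expect_equal(unname(b[, 1]), c(5.95, 95.05))
  k <- matrix(rep(3, 10), ncol = 1, dimnames = list(NULL, "k"))
  expect_equal(unname(quantile_bounds(k, 0.1)[, 1]), c(3, 3))
  expect_error(quantile_bounds(x, 0.5), "q must")
})

test_that("mahalanobis_d2 reduces to hand-computed quadratic forms", {
  expect_equal(mahalanobis_d2(c(1, 2), c(1, 2), diag(2)), 0)
  # p = 1: z-squared
  expect_equal(mahalanobis_d2(5, 3, matrix(4)), ((5 - 3) / 2)^2)
  # hand matrix-algebra oracle
  expect_equal(mahalanobis_d2(c(1, 2), c(0, 0),
                              matrix(c(1, 0, 0, 4), 2)), 1 + 4 / 4)
  expect_error(mahalanobis_d2(c(1, 2, 3), c(0, 0), diag(2)), "dimension")
  expect_message(d <- mahalanobis_d2(c(1, 1), c(0, 0),
                                     matrix(1, 2, 2)), "pseudo-inverse")
  expect_gte(d, 0)
})

test_that("Mahalanobis acceptance is chi-square calibrated under the null", {
  set.seed(601)
  R <- matrix(0.4, 3, 3); diag(R) <- 1
  orig <- make_correlated_features(5000, R)
  cand <- make_correlated_features(10000, R)
  res <- filter_candidates(cand, orig, rejection_criteria(q = 0, alpha = 0.025))
  expect_lt(abs(res$report$acceptance_rate - 0.975), 0.01)
  # candidate at the original mean is always accepted
  at_mean <- matrix(colMeans(orig), 1, dimnames = list("m", colnames(orig)))
  expect_true(filter_candidates(at_mean, orig,
                                rejection_criteria(q = 0.05,
                                                   alpha = 0.025))$accept)
  # gross single-feature outlier is quantile-rejected
  out <- at_mean
  out[1, 1] <- out[1, 1] + 10 * sd(orig[, 1])
  r2 <- filter_candidates(out, orig, rejection_criteria(q = 0.05, alpha = 0.5))
  expect_false(r2$accept)
  expect_equal(r2$report$n_rejected_quantile, 1)
})

test_that("quantile acceptance matches (1-2q)^p for independent features and counts conserve", {
  set.seed(602)
  p <- 3
  orig <- make_correlated_features(20000, diag(p))
  cand <- make_correlated_features(10000, diag(p))
  crit <- rejection_criteria(q = 0.05, alpha = 1e-9)  # Mahalanobis disabled
  res <- filter_candidates(cand, orig, crit)
  expect_lt(abs(res$report$acceptance_rate - (1 - 2 * 0.05)^p), 0.02)
  with(res$report, expect_equal(n_generated,
                                n_accepted + n_rejected_quantile +
                                  n_rejected_mahalanobis))
})

test_that("tightening q or alpha never grows the accepted set", {
  set.seed(603)
  orig <- make_correlated_features(3000, diag(2))
  cand <- make_correlated_features(3000, diag(2))
  acc <- function(q, a) {
    filter_candidates(cand, orig, rejection_criteria(q = q, alpha = a))$accept
  }
  loose <- acc(0.01, 0.01)
  tight_q <- acc(0.10, 0.01)
  tight_a <- acc(0.01, 0.20)
  expect_true(all(tight_q <= loose))
  expect_true(all(tight_a <= loose))
})

test_that("the sequence-driven rejection loop accepts faithful sets and reports shortfalls", {
  set.seed(604)
  fam <- make_sequence_family(60, alphabet = "dna",
                              length_law = list("unif", 150, 250),
                              concentration = c(8, 6, 6, 8))
  model <- fit_blueprint_model(fam)
  spec <- feature_spec(dinuc = c("twist", "nn_free_energy"), gc = TRUE)

  # filters effectively disabled: target met in one round
  res0 <- simulate_sequences_with_features(
    model, fam, spec, rejection_criteria(q = 0, alpha = 1e-9),
    target_n = 100, batch_size = 400)
  expect_equal(res0$report$iterations, 1L)
  expect_length(res0$sequences, 100)

  # default criteria: accepted features stay close to the originals
  res <- simulate_sequences_with_features(
    model, fam, spec, rejection_criteria(), target_n = 300,
    max_rounds = 10, batch_size = 1000)
  orig_feat <- extract_features(fam, spec)
  for (j in seq_len(ncol(orig_feat))) {
    expect_lt(ks_distance(res$features[, j], orig_feat[, j]), 0.2)
  }
  expect_identical(nrow(res$features), length(res$sequences))
  with(res$report, expect_equal(n_generated,
                                n_accepted + n_rejected_quantile +
                                  n_rejected_mahalanobis))

  # near-impossible criteria exercise the shortfall/diagnostic path
  expect_error(
    suppressWarnings(simulate_sequences_with_features(
      model, fam, spec, rejection_criteria(q = 0.49, alpha = 0.9999),
      target_n = 50, max_rounds = 2, batch_size = 200)),
    "no candidates accepted")
})
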