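# Monte Carlo rejection of simulated candidates in feature space.
#
# Two rules: (i) per-feature quantile bounds computed from the original data
# (two-sided tail mass q per feature), and (ii) a multivariate Mahalanobis
# distance rule against the original mean/covariance, thresholded at the
# chi-square quantile with df = number of features in the rule. Candidates
# failing either rule are rejected; the driver loop regenerates until the
# target count (or a round limit) is reached.

#' Rejection criteria for candidate filtering
#'
#' @param q Two-sided tail mass per feature for the quantile rule, in
#'   `[0, 0.5)`; 0 disables nothing but reduces the bounds to the observed
#'   min/max. Default 0.025.
#' @param alpha Mahalanobis tail probability in `(0, 1)`: candidates with
#'   squared distance beyond the chi-square `1 - alpha` quantile are
#'   rejected. Default 0.025.
#' @param cov_source `"sample"` (classical mean/covariance) or `"robust"`
#'   (MVE-based robust estimate via [MASS::cov.rob]).
#' @param subset Feature names (or indices) used by the Mahalanobis rule;
#'   `NULL` means all features. The rule needs at least 2 features and is
#'   skipped (with a message) below that.
#' @return An object of class `rejection_criteria`.
#' @export
rejection_criteria <- function(q = 0.025, alpha = 0.025,
                               cov_source = c("sample", "robust"),
                               subset = NULL) {
  cov_source <- match.arg(cov_source)
  if (!is.numeric(q) || q < 0 || q >= 0.5) stop("q must lie in [0, 0.5)")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)")
  }
  structure(list(q = q, alpha = alpha, cov_source = cov_source,
                 subset = subset),
            class = "rejection_criteria")
}

#' Per-feature quantile bounds of a feature matrix
#'
#' Empirical `q` and `1 - q` quantiles (linear interpolation, type 7) of each
#' feature.
#'
#' @param original Feature matrix with at least 5 rows.
#' @param q Tail mass in `[0, 0.5)`; `q = 0` gives the observed min/max.
#' @return 2 x p matrix with rows `low`, `high`.
#' @export
quantile_bounds <- function(original, q) {
  original <- as_feature_matrix(original)
  if (nrow(original) < 5L) stop("need at least 5 rows for quantile bounds")
  if (!is.numeric(q) || q < 0 || q >= 0.5) stop("q must lie in [0, 0.5)")
  b <- apply(original, 2, stats::quantile, probs = c(q, 1 - q), type = 7,
             names = FALSE)
  rownames(b) <- c("low", "high")
  b
}

#' Squared Mahalanobis distance
#'
#' `(x - mean)' cov^{-1} (x - mean)` for each row of `x`. A singular
#' covariance falls back to the Moore-Penrose pseudo-inverse with a message.
#'
#' @param x Numeric vector or matrix (rows = observations).
#' @param center Mean vector.
#' @param cov Covariance matrix.
#' @return Numeric vector of squared distances (>= 0).
#' @export
mahalanobis_d2 <- function(x, center, cov) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(center) || !all(dim(cov) == length(center))) {
    stop("dimension mismatch between x, center and cov")
  }
  inv <- tryCatch(solve(cov), error = function(e) NULL)
  if (is.null(inv)) {
    message("singular covariance: using pseudo-inverse")
    inv <- MASS::ginv(cov)
  }
  stats::mahalanobis(x, center, inv, inverted = TRUE)
}

#' Filter candidate rows against the original feature distribution
#'
#' A candidate is rejected if any feature falls outside its quantile bounds,
#' or if its squared Mahalanobis distance from the original mean (on the
#' criteria's feature subset) exceeds the chi-square `1 - alpha` quantile.
#'
#' @param candidates Feature matrix of candidates.
#' @param original Feature matrix of the original data (same feature names).
#' @param criteria A [rejection_criteria].
#' @return List with `accept` (logical mask over candidate rows) and `report`
#'   (a `rejection_report`: generated/accepted/rejected counts per rule and
#'   the acceptance rate).
#' @export
filter_candidates <- function(candidates, original, criteria) {
  stopifnot(inherits(criteria, "rejection_criteria"))
  candidates <- as_feature_matrix(candidates)
  original <- as_feature_matrix(original)
  if (!identical(colnames(candidates), colnames(original))) {
    stop("candidate and original feature names differ")
  }
  b <- quantile_bounds(original, criteria$q)
  ok_q <- rep(TRUE, nrow(candidates))
  for (j in seq_len(ncol(candidates))) {
    ok_q <- ok_q & candidates[, j] >= b["low", j] &
      candidates[, j] <= b["high", j]
  }

  subset <- criteria$subset
  if (is.null(subset)) subset <- colnames(original)
  if (is.numeric(subset)) subset <- colnames(original)[subset]
  ok_m <- rep(TRUE, nrow(candidates))
  if (length(subset) >= 2L) {
    sub_o <- original[, subset, drop = FALSE]
    if (criteria$cov_source == "robust") {
      rob <- MASS::cov.rob(sub_o)
      ctr <- rob$center
      cv <- rob$cov
    } else {
      ctr <- colMeans(sub_o)
      cv <- stats::cov(sub_o)
    }
    d2 <- mahalanobis_d2(candidates[, subset, drop = FALSE], ctr, cv)
    ok_m <- d2 <= stats::qchisq(1 - criteria$alpha, df = length(subset))
  } else {
    message("Mahalanobis rule skipped: fewer than 2 features in subset")
  }

  accept <- ok_q & ok_m
  report <- structure(list(
    n_generated = nrow(candidates),
    n_accepted = sum(accept),
    n_rejected_quantile = sum(!ok_q),
    n_rejected_mahalanobis = sum(ok_q & !ok_m),
    acceptance_rate = mean(accept),
    iterations = 1L), class = "rejection_report")
  list(accept = accept, report = report)
}

#' @export
print.rejection_report <- function(x, ...) {
  cat(sprintf(paste0("rejection_report: %d generated, %d accepted (%.1f%%); ",
                     "%d quantile-rejected, %d Mahalanobis-rejected, ",
                     "%d round(s)\n"),
              x$n_generated, x$n_accepted, 100 * x$acceptance_rate,
              x$n_rejected_quantile, x$n_rejected_mahalanobis, x$iterations))
  invisible(x)
}

merge_reports <- function(a, b) {
  structure(list(
    n_generated = a$n_generated + b$n_generated,
    n_accepted = a$n_accepted + b$n_accepted,
    n_rejected_quantile = a$n_rejected_quantile + b$n_rejected_quantile,
    n_rejected_mahalanobis = a$n_rejected_mahalanobis +
      b$n_rejected_mahalanobis,
    acceptance_rate = (a$n_accepted + b$n_accepted) /
      (a$n_generated + b$n_generated),
    iterations = a$iterations + b$iterations), class = "rejection_report")
}

#' Sequence-driven simulation of numerical features
#'
#' The full rejection loop: simulate candidate sequences (from a blueprint
#' model or a profile HMM), project them into feature space, filter against
#' the original sequences' features, and accumulate accepted candidates until
#' `target_n` are collected or `max_rounds` is exhausted. If the target is
#' not met a partial set is returned with a warning; zero acceptances across
#' all rounds is an error suggesting looser criteria.
#'
#' @param seq_model A `blueprint_model` or `profile_hmm`.
#' @param original_seqs The original [seq_set] defining the feature-space
#'   target.
#' @param spec A [feature_spec] compatible with the alphabet.
#' @param criteria A [rejection_criteria].
#' @param target_n Number of accepted sequences wanted.
#' @param max_rounds Maximum generation rounds (default 50).
#' @param batch_size Candidates per round (default `max(target_n, 1000)`).
#' @return List with `sequences` (accepted [seq_set]), `features` (their
#'   feature matrix) and `report` (cumulative `rejection_report`).
#' @export
simulate_sequences_with_features <- function(seq_model, original_seqs, spec,
                                             criteria = rejection_criteria(),
                                             target_n, max_rounds = 50L,
                                             batch_size = NULL) {
  stopifnot(inherits(original_seqs, "seq_set"),
            inherits(spec, "feature_spec"),
            inherits(criteria, "rejection_criteria"))
  if (!is.numeric(target_n) || target_n < 1) stop("target_n must be >= 1")
  if (is.null(batch_size)) batch_size <- max(target_n, 1000L)
  orig_feat <- extract_features(original_seqs, spec)

  gen <- function(n, tag) {
    if (inherits(seq_model, "blueprint_model")) {
      simulate_sequences(seq_model, n, prefix = tag)
    } else if (inherits(seq_model, "profile_hmm")) {
      sample_from_profile(seq_model, n, prefix = tag)
    } else {
      stop("seq_model must be a blueprint_model or profile_hmm")
    }
  }

  acc_seqs <- character(0)
  acc_feat <- NULL
  report <- NULL
  for (round in seq_len(max_rounds)) {
    cand <- gen(batch_size, sprintf("cand%02d", round))
    # pseudo-AA needs L > lambda: drop candidates too short to featurize
    if (!is.null(spec$pseaa_lambda)) {
      keep <- nchar(cand$sequences) > spec$pseaa_lambda
      if (!all(keep)) cand <- cand[keep]
      if (length(cand) == 0L) next
    }
    feat <- suppressWarnings(extract_features(cand, spec))
    res <- filter_candidates(feat, orig_feat, criteria)
    report <- if (is.null(report)) res$report else {
      merge_reports(report, res$report)
    }
    if (any(res$accept)) {
      acc_seqs <- c(acc_seqs, cand$sequences[res$accept])
      acc_feat <- rbind(acc_feat, feat[res$accept, , drop = FALSE])
    }
    if (length(acc_seqs) >= target_n) break
  }
  if (length(acc_seqs) == 0L) {
    stop(sprintf(paste0("no candidates accepted in %d round(s); loosen the ",
                        "criteria (q = %g, alpha = %g)"),
                 max_rounds, criteria$q, criteria$alpha))
  }
  if (length(acc_seqs) > target_n) {
    acc_seqs <- acc_seqs[seq_len(target_n)]
    acc_feat <- acc_feat[seq_len(target_n), , drop = FALSE]
  } else if (length(acc_seqs) < target_n) {
    warning(sprintf("shortfall: %d of %d requested sequences accepted",
                    length(acc_seqs), target_n))
  }
  names(acc_seqs) <- sprintf("sim_%06d", seq_along(acc_seqs))
  rownames(acc_feat) <- names(acc_seqs)
  list(sequences = seq_set(acc_seqs, alphabet = original_seqs$alphabet),
       features = acc_feat, report = report)
}
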