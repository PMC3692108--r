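# Diagnostics and validation machinery: rank correlation, normality
# detection, original-vs-simulated comparison, and reference binary
# classifiers (Gaussian naive Bayes, probabilistic neural networks) with
# accuracy / F-score / Matthews correlation metrics.

#' Spearman rank-correlation matrix
#'
#' Symmetric, unit-diagonal matrix of Spearman's rho (average ranks for
#' ties). Entries involving a constant feature are undefined and returned as
#' `NA` with a warning, never silently zeroed.
#'
#' @param data Feature matrix with at least 3 rows.
#' @return p x p numeric matrix.
#' @export
spearman_matrix <- function(data) {
  data <- as_feature_matrix(data)
  if (nrow(data) < 3L) stop("need at least 3 rows")
  const <- apply(data, 2, function(v) stats::sd(v) == 0)
  rho <- suppressWarnings(stats::cor(data, method = "spearman"))
  if (any(const)) {
    warning("constant feature(s) give undefined correlations (NA): ",
            paste(colnames(data)[const], collapse = ", "))
    rho[const, ] <- NA_real_
    rho[, const] <- NA_real_
  }
  diag(rho) <- 1
  rho
}

#' Univariate and multivariate normality detection
#'
#' Each feature is tested 1D with Shapiro-Wilk (subsampled to 5000 when
#' larger); each declared pair/triplet is tested with Mardia's multivariate
#' skewness and kurtosis statistics. A feature or group is flagged normal
#' when its test(s) do not reject at `alpha`.
#'
#' @param data Feature matrix with n >= 20.
#' @param groups Optional list of feature-name or index vectors of size 2
#'   or 3; larger groups are an error.
#' @param alpha Significance level (default 0.05).
#' @return List with `univariate` (data frame: feature, W, p_value, normal)
#'   and `multivariate` (data frame: group, skewness/kurtosis statistics and
#'   p-values, normal flag), or `NULL` if no groups given.
#' @export
normality_tests <- function(data, groups = NULL, alpha = 0.05) {
  data <- as_feature_matrix(data)
  n <- nrow(data)
  if (n < 20L) stop("need at least 20 rows for stable normality tests")
  uni <- do.call(rbind, lapply(colnames(data), function(f) {
    v <- data[, f]
    if (length(v) > 5000L) v <- v[seq(1, length(v), length.out = 5000L)]
    sw <- stats::shapiro.test(v)
    data.frame(feature = f, W = unname(sw$statistic),
               p_value = sw$p.value, normal = sw$p.value > alpha)
  }))
  mv <- NULL
  if (!is.null(groups)) {
    mv <- do.call(rbind, lapply(groups, function(g) {
      if (is.character(g)) g <- match(g, colnames(data))
      if (length(g) > 3L) {
        stop("multivariate normality groups are limited to size 2 or 3")
      }
      m <- mardia_test(data[, g, drop = FALSE])
      data.frame(group = paste(colnames(data)[g], collapse = ","),
                 skewness = m$skewness, skewness_p = m$skewness_p,
                 kurtosis = m$kurtosis, kurtosis_p = m$kurtosis_p,
                 normal = m$skewness_p > alpha & m$kurtosis_p > alpha)
    }))
  }
  list(univariate = uni, multivariate = mv)
}

# Mardia's multivariate skewness (chi-square) and kurtosis (normal) tests.
mardia_test <- function(x) {
  n <- nrow(x)
  p <- ncol(x)
  ctr <- scale(x, center = TRUE, scale = FALSE)
  S <- stats::cov(x) * (n - 1) / n
  inv <- solve(S)
  D <- ctr %*% inv %*% t(ctr)
  b1 <- sum(D^3) / n^2
  b2 <- mean(diag(D)^2)
  skew_stat <- n * b1 / 6
  skew_df <- p * (p + 1) * (p + 2) / 6
  kurt_z <- (b2 - p * (p + 2)) / sqrt(8 * p * (p + 2) / n)
  list(skewness = b1,
       skewness_p = stats::pchisq(skew_stat, skew_df, lower.tail = FALSE),
       kurtosis = b2,
       kurtosis_p = 2 * stats::pnorm(abs(kurt_z), lower.tail = FALSE))
}

#' Compare an original and a simulated feature matrix
#'
#' Computes per-feature two-sample KS statistics, the Spearman matrices of
#' both sets and their absolute difference, Freedman-Diaconis histogram break
#' specifications on the pooled data, and 1D normality flags for the
#' original.
#'
#' @param original,simulated Feature matrices with identical feature names.
#' @return An object of class `comparison_report`.
#' @export
compare_sets <- function(original, simulated) {
  original <- as_feature_matrix(original)
  simulated <- as_feature_matrix(simulated)
  if (!identical(colnames(original), colnames(simulated))) {
    stop("feature names differ between the two sets")
  }
  ks <- vapply(colnames(original), function(f) {
    ks_distance(original[, f], simulated[, f])
  }, 0)
  rho_o <- suppressWarnings(spearman_matrix(original))
  rho_s <- suppressWarnings(spearman_matrix(simulated))
  bins <- lapply(colnames(original), function(f) {
    pooled <- c(original[, f], simulated[, f])
    nb <- max(1L, grDevices::nclass.FD(pooled))
    seq(min(pooled), max(pooled), length.out = nb + 1L)
  })
  names(bins) <- colnames(original)
  norm_flags <- if (nrow(original) >= 20L) {
    normality_tests(original)$univariate
  }
  structure(list(ks = ks, spearman_original = rho_o,
                 spearman_simulated = rho_s,
                 spearman_abs_diff = abs(rho_o - rho_s),
                 histogram_breaks = bins, normality = norm_flags),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("comparison_report\n")
  cat(sprintf("  per-feature KS: max %.4f (feature '%s')\n",
              max(x$ks), names(x$ks)[which.max(x$ks)]))
  off <- x$spearman_abs_diff[upper.tri(x$spearman_abs_diff)]
  if (length(off)) {
    cat(sprintf("  max |delta Spearman rho|: %.4f\n",
                max(off, na.rm = TRUE)))
  }
  invisible(x)
}

#' Train a reference binary classifier
#'
#' Three kinds: Gaussian naive Bayes (per-class per-feature mean/variance
#' with a variance floor of 1e-9), and probabilistic neural networks (Parzen
#' kernel density classifiers) with a Gaussian
#' (`exp(-||x - xi||^2 / (2 sigma^2))`) or Exponential
#' (`exp(-||x - xi|| / sigma)`) kernel. PNN bandwidth defaults to the mean
#' nearest-neighbor distance of the training points. Class priors are the
#' training label frequencies.
#'
#' @param train Feature matrix.
#' @param labels Binary vector (0/1, logical or 2-level factor), both classes
#'   present.
#' @param kind `"gaussian_naive_bayes"`, `"pnn_gaussian"` or
#'   `"pnn_exponential"`.
#' @param sigma PNN kernel bandwidth (> 0); `NULL` for the default.
#' @return An object of class `classifier_model` with a [predict] method
#'   returning 0/1 labels.
#' @export
train_classifier <- function(train, labels,
                             kind = c("gaussian_naive_bayes", "pnn_gaussian",
                                      "pnn_exponential"),
                             sigma = NULL) {
  kind <- match.arg(kind)
  train <- as_feature_matrix(train)
  y <- normalize_labels(labels)
  if (length(y) != nrow(train)) stop("labels length must match rows")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  priors <- c(`0` = mean(y == 0), `1` = mean(y == 1))
  model <- list(kind = kind, priors = priors,
                feature_names = colnames(train))
  if (kind == "gaussian_naive_bayes") {
    stats_by <- lapply(c(0, 1), function(cl) {
      x <- train[y == cl, , drop = FALSE]
      v <- apply(x, 2, stats::var)
      if (any(v < 1e-9)) {
        message("zero-variance feature in class ", cl,
                ": variance floored at 1e-9")
        v <- pmax(v, 1e-9)
      }
      list(mean = colMeans(x), var = v)
    })
    names(stats_by) <- c("0", "1")
    model$class_stats <- stats_by
  } else {
    if (is.null(sigma)) {
      d <- as.matrix(stats::dist(train))
      diag(d) <- Inf
      sigma <- mean(apply(d, 1, min))
      if (!is.finite(sigma) || sigma <= 0) sigma <- 1
    }
    if (sigma <= 0) stop("sigma must be > 0")
    model$sigma <- sigma
    model$points <- list(`0` = train[y == 0, , drop = FALSE],
                         `1` = train[y == 1, , drop = FALSE])
  }
  structure(model, class = "classifier_model")
}

normalize_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  if (is.logical(labels)) labels <- as.integer(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be binary (0/1)")
  as.integer(labels)
}

#' @export
print.classifier_model <- function(x, ...) {
  cat(sprintf("classifier_model (%s), priors %.2f/%.2f", x$kind,
              x$priors[1], x$priors[2]))
  if (!is.null(x$sigma)) cat(sprintf(", sigma = %.4g", x$sigma))
  cat("\n")
  invisible(x)
}

#' Predict class labels with a reference classifier
#'
#' @param object A [train_classifier] result.
#' @param newdata Feature matrix with the training feature names.
#' @param ... Ignored.
#' @return Integer vector of 0/1 labels.
#' @export
predict.classifier_model <- function(object, newdata, ...) {
  newdata <- as_feature_matrix(newdata)
  newdata <- newdata[, object$feature_names, drop = FALSE]
  score <- function(cl) {
    if (object$kind == "gaussian_naive_bayes") {
      st <- object$class_stats[[cl]]
      ll <- rowSums(vapply(seq_along(st$mean), function(j) {
        stats::dnorm(newdata[, j], st$mean[j], sqrt(st$var[j]), log = TRUE)
      }, numeric(nrow(newdata))))
      log(object$priors[[cl]]) + ll
    } else {
      pts <- object$points[[cl]]
      s <- object$sigma
      k <- vapply(seq_len(nrow(pts)), function(i) {
        d2 <- rowSums(sweep(newdata, 2, pts[i, ])^2)
        if (object$kind == "pnn_gaussian") exp(-d2 / (2 * s^2))
        else exp(-sqrt(d2) / s)
      }, numeric(nrow(newdata)))
      k <- matrix(k, nrow = nrow(newdata))
      log(object$priors[[cl]]) + log(rowMeans(k) + 1e-300)
    }
  }
  s0 <- score("0")
  s1 <- score("1")
  as.integer(s1 > s0)
}

#' Binary classification metrics
#'
#' Accuracy, F-score and Matthews correlation coefficient from the confusion
#' matrix of predicted versus actual binary labels. When a confusion-matrix
#' marginal is zero the MCC is undefined and returned as 0 with attribute
#' `mcc_undefined = TRUE`.
#'
#' @param predicted,actual Equal-length binary vectors.
#' @return Named numeric vector `c(accuracy, f_score, mcc)`.
#' @export
classification_metrics <- function(predicted, actual) {
  predicted <- normalize_labels(predicted)
  actual <- normalize_labels(actual)
  if (length(predicted) != length(actual)) {
    stop("predicted and actual must have equal length")
  }
  tp <- sum(predicted == 1 & actual == 1)
  tn <- sum(predicted == 0 & actual == 0)
  fp <- sum(predicted == 1 & actual == 0)
  fn <- sum(predicted == 0 & actual == 1)
  n <- length(actual)
  acc <- (tp + tn) / n
  f <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  out <- c(accuracy = acc, f_score = f,
           mcc = if (denom == 0) 0 else (tp * tn - fp * fn) / denom)
  if (denom == 0) attr(out, "mcc_undefined") <- TRUE
  out
}

#' Exhaustive feature-subset classifier evaluation
#'
#' Trains and evaluates a classifier on every non-empty subset of the
#' features (at most 10 features) and ranks the subsets by MCC, then
#' F-score.
#'
#' @param train,test Feature matrices sharing feature names.
#' @param train_labels,test_labels Binary label vectors.
#' @param kind Classifier kind (see [train_classifier]).
#' @param sigma Optional PNN bandwidth.
#' @return Data frame with columns `features`, `accuracy`, `f_score`, `mcc`,
#'   sorted best-first.
#' @export
feature_combination_search <- function(train, test, train_labels, test_labels,
                                       kind = "gaussian_naive_bayes",
                                       sigma = NULL) {
  train <- as_feature_matrix(train)
  test <- as_feature_matrix(test)
  p <- ncol(train)
  if (p > 10L) stop("exhaustive search is limited to 10 features")
  subsets <- unlist(lapply(seq_len(p), function(k) {
    utils::combn(colnames(train), k, simplify = FALSE)
  }), recursive = FALSE)
  rows <- lapply(subsets, function(fs) {
    m <- train_classifier(train[, fs, drop = FALSE], train_labels, kind,
                          sigma = sigma)
    pred <- predict(m, test[, fs, drop = FALSE])
    met <- classification_metrics(pred, test_labels)
    data.frame(features = paste(fs, collapse = "+"),
               accuracy = met[["accuracy"]], f_score = met[["f_score"]],
               mcc = met[["mcc"]])
  })
  out <- do.call(rbind, rows)
  out[order(-out$mcc, -out$f_score), , drop = FALSE]
}
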