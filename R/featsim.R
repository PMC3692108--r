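# Correlated feature simulation through a Gaussian copula.
#
# Marginals are fitted per feature with fit_density(); the dependence target
# is the Spearman rank-correlation matrix, mapped to the normal-score scale
# by the exact transform r = 2 sin(pi * rho / 6) and factored by Cholesky
# decomposition. Features can be simulated independently (1D), in pairwise
# (2D) or triplet (3D) groups — groups are jointly simulated, independent
# between groups — or as one full joint copula.

#' Fit a correlation model to a feature matrix
#'
#' @param data Numeric feature matrix (samples x features), n >= 10.
#' @param mode Grouping mode: `"full"` (one joint copula over all features),
#'   `"independent_1d"`, `"pairwise_2d"` or `"triplet_3d"`.
#' @param groups For the 2D/3D modes, a list of feature-name (or index)
#'   pairs/triplets; when `NULL`, groups are auto-formed greedily from the
#'   strongest absolute Spearman correlations. Features left over are
#'   simulated independently.
#' @param marginal_kind Density kind for the marginals (see [fit_density]).
#' @return An object of class `correlation_model`: `feature_names`,
#'   `marginals`, `rho` (Spearman target), `r` (normal-score scale), `groups`
#'   (list of index vectors), `chol` (per-group lower-triangular factors),
#'   `repair_distance` (Frobenius distance moved by any positive-definite
#'   repair).
#' @export
fit_correlation_model <- function(data,
                                  mode = c("full", "independent_1d",
                                           "pairwise_2d", "triplet_3d"),
                                  groups = NULL, marginal_kind = "auto") {
  mode <- match.arg(mode)
  data <- as_feature_matrix(data)
  n <- nrow(data)
  p <- ncol(data)
  if (n < 10L) stop("need at least 10 rows to fit a correlation model")
  sds <- apply(data, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant feature(s): ",
         paste(colnames(data)[sds == 0], collapse = ", "))
  }
  marginals <- lapply(seq_len(p), function(j) {
    suppressWarnings(fit_density(data[, j], kind = marginal_kind))
  })
  names(marginals) <- colnames(data)
  rho <- stats::cor(data, method = "spearman")
  r <- 2 * sin(pi * rho / 6)
  diag(r) <- 1

  idx_groups <- resolve_groups(mode, groups, rho, colnames(data))
  repair_distance <- 0
  chol_factors <- lapply(idx_groups, function(g) {
    if (length(g) == 1L) return(matrix(1, 1, 1))
    sub <- r[g, g, drop = FALSE]
    res <- chol_with_repair(sub)
    if (res$repaired) {
      repair_distance <<- repair_distance + res$distance
      message(sprintf(
        "correlation block [%s] repaired to positive definite (Frobenius %.3g)",
        paste(colnames(data)[g], collapse = ", "), res$distance))
    }
    res$L
  })
  structure(list(feature_names = colnames(data), marginals = marginals,
                 rho = rho, r = r, mode = mode, groups = idx_groups,
                 chol = chol_factors, repair_distance = repair_distance,
                 n_fit = n),
            class = "correlation_model")
}

# Build the list of feature-index groups for a mode; auto-group by greedy
# strongest-|rho| pairing when groups are not supplied.
resolve_groups <- function(mode, groups, rho, fnames) {
  p <- length(fnames)
  if (mode == "full") return(list(seq_len(p)))
  if (mode == "independent_1d") return(as.list(seq_len(p)))
  size <- if (mode == "pairwise_2d") 2L else 3L
  if (!is.null(groups)) {
    idx <- lapply(groups, function(g) {
      i <- if (is.character(g)) match(g, fnames) else as.integer(g)
      if (any(is.na(i)) || any(i < 1 | i > p)) {
        stop("unknown feature in group: ", paste(g, collapse = ", "))
      }
      if (length(i) != size) {
        stop(sprintf("mode %s requires groups of size %d", mode, size))
      }
      i
    })
    used <- unlist(idx)
    if (anyDuplicated(used)) stop("groups must not overlap")
    return(c(idx, as.list(setdiff(seq_len(p), used))))
  }
  # greedy: repeatedly take the strongest remaining |rho| pair, extend to a
  # triplet (3D mode) with the feature most correlated to both members
  a <- abs(rho)
  diag(a) <- 0
  remaining <- seq_len(p)
  out <- list()
  while (length(remaining) >= size) {
    sub <- a[remaining, remaining, drop = FALSE]
    ij <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    g <- remaining[ij]
    if (size == 3L) {
      rest <- setdiff(remaining, g)
      scores <- a[g[1], rest] + a[g[2], rest]
      g <- c(g, rest[which.max(scores)])
    }
    out <- c(out, list(unname(g)))
    remaining <- setdiff(remaining, g)
  }
  c(out, as.list(remaining))
}

# Lower-triangular Cholesky factor, repairing non-positive-definite inputs by
# eigenvalue clipping (floor 1e-10) and rescaling to unit diagonal.
chol_with_repair <- function(R) {
  L <- tryCatch(t(chol(R)), error = function(e) NULL)
  if (!is.null(L)) return(list(L = L, repaired = FALSE, distance = 0))
  e <- eigen(R, symmetric = TRUE)
  vals <- pmax(e$values, 1e-10)
  R2 <- e$vectors %*% diag(vals, length(vals)) %*% t(e$vectors)
  R2 <- stats::cov2cor(R2)
  list(L = t(chol(R2 + diag(1e-12, nrow(R2)))), repaired = TRUE,
       distance = norm(R2 - R, "F"))
}

#' @export
print.correlation_model <- function(x, ...) {
  cat(sprintf("correlation_model: %d features, mode %s, %d group(s)\n",
              length(x$feature_names), x$mode, length(x$groups)))
  if (x$repair_distance > 0) {
    cat(sprintf("  positive-definite repair distance: %.3g\n",
                x$repair_distance))
  }
  invisible(x)
}

#' Simulate a feature matrix from a correlation model
#'
#' For each group, independent standard normals are colored by the group's
#' Cholesky factor, mapped to uniforms by the normal CDF, and pushed through
#' each feature's fitted marginal quantile function — so marginals are
#' preserved exactly in law while rank correlations match the target.
#' Consumes the R random number stream.
#'
#' @param model A [fit_correlation_model] result.
#' @param n Number of rows to simulate (>= 1).
#' @param prefix Row-identifier prefix.
#' @return Numeric matrix `n` x p with the original feature names.
#' @export
simulate_features <- function(model, n, prefix = "sim") {
  stopifnot(inherits(model, "correlation_model"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  p <- length(model$feature_names)
  out <- matrix(NA_real_, n, p,
                dimnames = list(sprintf("%s_%06d", prefix, seq_len(n)),
                                model$feature_names))
  for (gi in seq_along(model$groups)) {
    g <- model$groups[[gi]]
    d <- length(g)
    if (d == 1L) {
      out[, g] <- sample_density(model$marginals[[g]], n)
      next
    }
    eps <- matrix(stats::rnorm(n * d), nrow = d)
    z <- model$chol[[gi]] %*% eps
    u <- stats::pnorm(z)
    for (k in seq_len(d)) {
      out[, g[k]] <- density_quantile(model$marginals[[g[k]]], u[k, ])
    }
  }
  out
}
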