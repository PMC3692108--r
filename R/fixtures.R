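# Deterministic synthetic-data generators: sequence families and correlated
# feature matrices with known ground truth. These are first-class generators
# (used by the documentation, the test suite and the acceptance script) and
# are implemented independently of the simulation code paths they are used
# to validate: make_correlated_features() uses parametric quantile functions
# and MASS::mvrnorm, not the fitted-density copula of simulate_features().

#' Generate a synthetic sequence family
#'
#' Produces `n` records whose per-record composition is drawn from a
#' Dirichlet distribution over the alphabet's core symbols, with lengths from
#' a named law and an optional motif implanted at a random position with
#' per-position mutation.
#'
#' @param n Number of records.
#' @param alphabet `"dna"`, `"rna"` or `"protein"`.
#' @param length_law List naming the length distribution and its parameters:
#'   `list("fixed", length)`, `list("unif", min, max)`,
#'   `list("nbinom", size, mu)` (shifted so lengths are >= 1) or
#'   `list("lnorm", meanlog, sdlog)`.
#' @param concentration Dirichlet concentration vector over the core symbols
#'   (default: uniform with concentration 5).
#' @param motif Optional residue string implanted in every record.
#' @param motif_mutation Per-position probability of mutating an implanted
#'   motif residue (default 0).
#' @param seed Optional seed applied via `set.seed` before generation.
#' @return A [seq_set] of `n` records named `fam_000001`, ...
#' @export
make_sequence_family <- function(n, alphabet = "dna",
                                 length_law = list("unif", 80, 200),
                                 concentration = NULL, motif = NULL,
                                 motif_mutation = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  syms <- alphabet_symbols(alphabet)
  if (is.null(concentration)) concentration <- rep(5, length(syms))
  stopifnot(length(concentration) == length(syms), all(concentration > 0),
            motif_mutation >= 0, motif_mutation <= 1)
  lens <- sample_length_law(n, length_law)
  if (!is.null(motif)) {
    motif <- toupper(motif)
    if (nchar(motif) > min(lens)) {
      stop("motif longer than the shortest generated length")
    }
  }
  # Dirichlet draws via normalized gammas
  g <- matrix(stats::rgamma(n * length(syms),
                            shape = rep(concentration, each = n)),
              nrow = n)
  comp <- g / rowSums(g)
  seqs <- vapply(seq_len(n), function(i) {
    chars <- sample(syms, lens[i], replace = TRUE, prob = comp[i, ])
    if (!is.null(motif)) {
      mchars <- strsplit(motif, "")[[1]]
      mut <- stats::runif(length(mchars)) < motif_mutation
      if (any(mut)) {
        mchars[mut] <- sample(syms, sum(mut), replace = TRUE)
      }
      pos <- sample.int(lens[i] - length(mchars) + 1L, 1L)
      chars[pos:(pos + length(mchars) - 1L)] <- mchars
    }
    paste(chars, collapse = "")
  }, "")
  names(seqs) <- sprintf("fam_%06d", seq_len(n))
  seq_set(seqs, alphabet = alphabet)
}

sample_length_law <- function(n, law) {
  name <- law[[1]]
  switch(name,
    fixed = rep(as.integer(law[[2]]), n),
    unif = sample(seq.int(law[[2]], law[[3]]), n, replace = TRUE),
    nbinom = 1L + stats::rnbinom(n, size = law[[2]], mu = law[[3]]),
    lnorm = pmax(1L, as.integer(round(stats::rlnorm(n, law[[2]], law[[3]])))),
    stop("unknown length law: ", name))
}

#' Parametric marginal specification for synthetic features
#'
#' @param kind `"normal"`, `"exponential"`, `"uniform"` or
#'   `"normal_mixture"` (bimodal two-component mixture).
#' @param ... Parameters: `mean`/`sd` (normal), `rate` (exponential),
#'   `min`/`max` (uniform), `means`/`sds`/`weights` (mixture).
#' @return A list with a quantile function `q(p)`, used by
#'   [make_correlated_features].
#' @export
marginal_spec <- function(kind = c("normal", "exponential", "uniform",
                                   "normal_mixture"), ...) {
  kind <- match.arg(kind)
  pars <- list(...)
  q <- switch(kind,
    normal = function(p) stats::qnorm(p, pars$mean %||% 0, pars$sd %||% 1),
    exponential = function(p) stats::qexp(p, pars$rate %||% 1),
    uniform = function(p) stats::qunif(p, pars$min %||% 0, pars$max %||% 1),
    normal_mixture = mixture_quantile(pars$means %||% c(-2, 2),
                                      pars$sds %||% c(1, 1),
                                      pars$weights %||% c(0.5, 0.5)))
  list(kind = kind, pars = pars, q = q)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Numeric inversion of a two-component normal-mixture CDF on a fine grid.
mixture_quantile <- function(means, sds, weights) {
  weights <- weights / sum(weights)
  lo <- min(means - 6 * sds)
  hi <- max(means + 6 * sds)
  grid <- seq(lo, hi, length.out = 4096L)
  cdf <- Reduce(`+`, lapply(seq_along(means), function(k) {
    weights[k] * stats::pnorm(grid, means[k], sds[k])
  }))
  cdf <- cummax(cdf)
  function(p) stats::approx(cdf, grid, xout = p, ties = "ordered",
                            rule = 2)$y
}

#' Generate a feature matrix with known correlation ground truth
#'
#' Ground-truth Gaussian-copula sampler: draws multivariate normals with the
#' given correlation matrix via [MASS::mvrnorm], maps them to uniforms and
#' pushes each column through a parametric marginal quantile function. This
#' path shares the copula mathematics with [simulate_features] but none of
#' its code (parametric quantiles versus fitted-density grids), so the two
#' can validate each other.
#'
#' @param n Number of rows.
#' @param R Valid correlation matrix (p x p, positive semi-definite).
#' @param marginals List of `p` [marginal_spec] objects (default: standard
#'   normals).
#' @param feature_names Optional column names.
#' @param seed Optional seed applied via `set.seed`.
#' @return Numeric n x p matrix.
#' @export
make_correlated_features <- function(n, R, marginals = NULL,
                                     feature_names = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  R <- as.matrix(R)
  p <- ncol(R)
  stopifnot(nrow(R) == p, all(abs(diag(R) - 1) < 1e-12))
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("R is not positive semi-definite")
  }
  if (is.null(marginals)) {
    marginals <- replicate(p, marginal_spec("normal"), simplify = FALSE)
  }
  stopifnot(length(marginals) == p)
  z <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = R)
  z <- matrix(z, nrow = n)
  u <- stats::pnorm(z)
  x <- vapply(seq_len(p), function(j) marginals[[j]]$q(u[, j]), numeric(n))
  x <- matrix(x, nrow = n)
  colnames(x) <- feature_names %||% sprintf("f%d", seq_len(p))
  rownames(x) <- sprintf("row_%06d", seq_len(n))
  x
}

#' Generate a labelled two-class feature family
#'
#' Two correlated Gaussian-copula classes with shifted means, as ground truth
#' for classifier round-trip experiments.
#'
#' @param n_per_class Rows per class.
#' @param p Number of features.
#' @param shift Mean shift of class 1 relative to class 0 (per feature).
#' @param rho Common within-class correlation (exchangeable structure).
#' @param seed Optional seed.
#' @return List with `features` (matrix, 2 * n_per_class rows) and `labels`
#'   (0/1 vector).
#' @export
make_two_class_features <- function(n_per_class, p = 4, shift = 1.5,
                                    rho = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  R <- matrix(rho, p, p)
  diag(R) <- 1
  m0 <- replicate(p, marginal_spec("normal", mean = 0, sd = 1),
                  simplify = FALSE)
  m1 <- replicate(p, marginal_spec("normal", mean = shift, sd = 1),
                  simplify = FALSE)
  x0 <- make_correlated_features(n_per_class, R, m0)
  x1 <- make_correlated_features(n_per_class, R, m1)
  x <- rbind(x0, x1)
  rownames(x) <- sprintf("row_%06d", seq_len(nrow(x)))
  list(features = x, labels = rep(c(0L, 1L), each = n_per_class))
}
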