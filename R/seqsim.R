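# De novo Monte Carlo sequence simulation.
#
# Each original sequence contributes one length and one composition vector;
# the per-characteristic distributions are fitted with fit_density() and
# sampled to produce a "blueprint" (length, composition) for every simulated
# sequence, whose residues are then drawn i.i.d. from the blueprint
# composition. Order structure is deliberately not modelled here: that is the
# profile-HMM module's job.

#' Fit a blueprint model to a sequence set
#'
#' Fits the length distribution and, for every core symbol of the alphabet, the
#' distribution of per-record symbol fractions. Ambiguity symbols (`N`/`X`)
#' are excluded from the composition denominators.
#'
#' @param seqs A [seq_set] with at least 2 records.
#' @param kind Density kind passed to [fit_density] (default `"auto"`).
#' @return An object of class `blueprint_model` with elements `alphabet`,
#'   `length_density` and `composition_densities` (one per core symbol).
#' @export
fit_blueprint_model <- function(seqs, kind = "auto") {
  stopifnot(inherits(seqs, "seq_set"))
  if (length(seqs) < 2L) stop("need at least 2 sequences to fit a model")
  syms <- alphabet_symbols(seqs$alphabet)
  comp <- composition_fractions(seqs)
  lens <- nchar(seqs$sequences)
  length_density <- suppressWarnings(
    fit_density(lens, bounds = c(1, Inf), kind = kind))
  comp_densities <- lapply(syms, function(s) {
    suppressWarnings(fit_density(comp[, s], bounds = c(0, 1), kind = kind))
  })
  names(comp_densities) <- syms
  structure(list(alphabet = seqs$alphabet, length_density = length_density,
                 composition_densities = comp_densities),
            class = "blueprint_model")
}

# Per-record core-symbol fractions, ambiguity symbols excluded from the
# denominator.
composition_fractions <- function(seqs) {
  syms <- alphabet_symbols(seqs$alphabet)
  out <- t(vapply(seqs$sequences, function(s) {
    chars <- strsplit(s, "")[[1]]
    chars <- chars[chars %in% syms]
    if (length(chars) == 0L) return(rep(1 / length(syms), length(syms)))
    tab <- table(factor(chars, levels = syms))
    as.numeric(tab) / length(chars)
  }, numeric(length(syms))))
  colnames(out) <- syms
  out
}

#' @export
print.blueprint_model <- function(x, ...) {
  cat(sprintf("blueprint_model (%s): length density [%s], %d composition densities\n",
              toupper(x$alphabet), x$length_density$kind,
              length(x$composition_densities)))
  invisible(x)
}

#' Sample sequence blueprints from a fitted model
#'
#' Each blueprint is a (length, composition) pair: the length is drawn from
#' the fitted length density and rounded (minimum 1); the composition is drawn
#' per symbol from its fitted density, clipped at 0 and renormalized to sum
#' to 1.
#'
#' @param model A [fit_blueprint_model] result.
#' @param n Number of blueprints (>= 1).
#' @return A list with `lengths` (integer vector) and `compositions`
#'   (`n` x symbols matrix, rows summing to 1).
#' @export
sample_blueprints <- function(model, n) {
  stopifnot(inherits(model, "blueprint_model"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  lens <- pmax(1L, as.integer(round(sample_density(model$length_density, n))))
  syms <- names(model$composition_densities)
  comp <- vapply(model$composition_densities,
                 function(d) pmax(0, sample_density(d, n)),
                 numeric(n))
  comp <- matrix(comp, nrow = n, dimnames = list(NULL, syms))
  tot <- rowSums(comp)
  tries <- 0L
  while (any(tot == 0)) {
    tries <- tries + 1L
    if (tries > 100L) stop("could not sample a non-zero composition vector")
    bad <- which(tot == 0)
    for (j in seq_along(syms)) {
      comp[bad, j] <- pmax(0, sample_density(model$composition_densities[[j]],
                                             length(bad)))
    }
    tot <- rowSums(comp)
  }
  comp <- comp / tot
  list(lengths = lens, compositions = comp)
}

#' Generate one sequence from a blueprint
#'
#' Residues are drawn independently and identically from the blueprint
#' composition.
#'
#' @param length Positive integer sequence length.
#' @param composition Probability vector over the alphabet's core symbols.
#' @param alphabet `"dna"`, `"rna"` or `"protein"`.
#' @return A single residue string.
#' @export
generate_sequence <- function(length, composition, alphabet) {
  syms <- alphabet_symbols(alphabet)
  stopifnot(length >= 1, length(composition) == length(syms),
            all(composition >= 0), abs(sum(composition) - 1) < 1e-6)
  paste(sample(syms, length, replace = TRUE, prob = composition),
        collapse = "")
}

#' Simulate a set of sequences from a blueprint model
#'
#' @param model A [fit_blueprint_model] result.
#' @param n Number of sequences to simulate (>= 1).
#' @param prefix Identifier prefix; records are named `<prefix>_000001`, ...
#' @return A [seq_set] of `n` simulated records.
#' @export
simulate_sequences <- function(model, n, prefix = "sim") {
  stopifnot(inherits(model, "blueprint_model"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  bp <- sample_blueprints(model, n)
  seqs <- vapply(seq_len(n), function(i) {
    generate_sequence(bp$lengths[i], bp$compositions[i, ], model$alphabet)
  }, "")
  names(seqs) <- sprintf("%s_%06d", prefix, seq_len(n))
  seq_set(seqs, alphabet = model$alphabet)
}

# Pooled per-symbol residue frequencies of a sequence set (core symbols only).
pooled_frequencies <- function(seqs) {
  syms <- alphabet_symbols(seqs$alphabet)
  chars <- strsplit(paste(seqs$sequences, collapse = ""), "")[[1]]
  chars <- chars[chars %in% syms]
  tab <- table(factor(chars, levels = syms))
  as.numeric(tab) / length(chars)
}
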