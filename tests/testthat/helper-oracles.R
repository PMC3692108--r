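# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# Double-loop pseudo-amino-acid composition, computed from first principles.
oracle_pseudo_aa <- function(seq, lambda, w, scales) {
  aa <- rownames(scales)
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  f <- numeric(length(aa))
  for (a in seq_along(aa)) f[a] <- sum(chars == aa[a]) / L
  theta <- numeric(lambda)
  for (j in seq_len(lambda)) {
    acc <- 0
    for (i in seq_len(L - j)) {
      d <- 0
      for (s in seq_len(ncol(scales))) {
        d <- d + (scales[chars[i + j], s] - scales[chars[i], s])^2
      }
      acc <- acc + d / ncol(scales)
    }
    theta[j] <- acc / (L - j)
  }
  denom <- sum(f) + w * sum(theta)
  c(f / denom, w * theta / denom)
}

# Naive window-loop dinucleotide property average.
oracle_dinuc <- function(seq, table, property) {
  chars <- strsplit(chartr("U", "T", seq), "")[[1]]
  vals <- c()
  for (i in seq_len(length(chars) - 1)) {
    di <- paste0(chars[i], chars[i + 1])
    if (di %in% colnames(table)) vals <- c(vals, table[property, di])
  }
  mean(vals)
}

# Brute-force confusion-matrix metrics.
oracle_metrics <- function(pred, actual) {
  tp <- 0; tn <- 0; fp <- 0; fn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && actual[i] == 1) tp <- tp + 1
    if (pred[i] == 0 && actual[i] == 0) tn <- tn + 1
    if (pred[i] == 1 && actual[i] == 0) fp <- fp + 1
    if (pred[i] == 0 && actual[i] == 1) fn <- fn + 1
  }
  acc <- (tp + tn) / length(pred)
  f <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  c(acc, f, mcc)
}

# A small diverse DNA family used by several tests.
toy_dna_family <- function(n = 50, seed = 421) {
  make_sequence_family(n, alphabet = "dna",
                       length_law = list("unif", 80, 200),
                       concentration = c(6, 4, 4, 6), seed = seed)
}
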