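# Sequence-to-feature projection: pseudo-amino-acid composition for proteins,
# dinucleotide physicochemical property averages and GC content for
# nucleotide sequences.

DINUCS <- c("AA", "AC", "AG", "AT", "CA", "CC", "CG", "CT",
            "GA", "GC", "GG", "GT", "TA", "TC", "TG", "TT")

#' Classical amino-acid property scales for pseudo-AA composition
#'
#' Hydrophobicity, hydrophilicity (Hopp-Woods) and side-chain mass for the 20
#' standard amino acids — the three scales of the classical pseudo-amino-acid
#' composition formulation. Each scale is standardized (mean 0, unit SD over
#' the 20 residues) before use when `standardized = TRUE`.
#'
#' @param standardized Standardize each scale over the 20 residues?
#' @return A 20 x 3 numeric matrix, rows named by one-letter amino-acid code,
#'   columns `hydrophobicity`, `hydrophilicity`, `side_chain_mass`.
#' @export
aa_property_scales <- function(standardized = TRUE) {
  aa <- AA_CORE
  hydrophobicity <- c(A = 0.62, R = -2.53, N = -0.78, D = -0.90, C = 0.29,
                      Q = -0.85, E = -0.74, G = 0.48, H = -0.40, I = 1.38,
                      L = 1.06, K = -1.50, M = 0.64, F = 1.19, P = 0.12,
                      S = -0.18, T = -0.05, W = 0.81, Y = 0.26, V = 1.08)
  hydrophilicity <- c(A = -0.5, R = 3.0, N = 0.2, D = 3.0, C = -1.0,
                      Q = 0.2, E = 3.0, G = 0.0, H = -0.5, I = -1.8,
                      L = -1.8, K = 3.0, M = -1.3, F = -2.5, P = 0.0,
                      S = 0.3, T = -0.4, W = -3.4, Y = -2.3, V = -1.5)
  side_chain_mass <- c(A = 15.0, R = 101.0, N = 58.0, D = 59.0, C = 47.0,
                       Q = 72.0, E = 73.0, G = 1.0, H = 82.0, I = 57.0,
                       L = 57.0, K = 73.0, M = 75.0, F = 91.0, P = 42.0,
                       S = 31.0, T = 45.0, W = 130.0, Y = 107.0, V = 43.0)
  m <- cbind(hydrophobicity = hydrophobicity[aa],
             hydrophilicity = hydrophilicity[aa],
             side_chain_mass = side_chain_mass[aa])
  rownames(m) <- aa
  if (standardized) m <- apply(m, 2, function(v) (v - mean(v)) / stats::sd(v))
  m
}

#' Pseudo-amino-acid composition of one protein sequence
#'
#' Computes the 20 amino-acid frequencies augmented with `lambda`
#' sequence-order correlation factors. The j-th factor is the mean, over all
#' residue pairs j positions apart, of the squared property difference
#' averaged across the supplied standardized scales. The full vector is
#' normalized so its `20 + lambda` components sum to 1: the first 20 are
#' `f_u / (sum f + w sum theta)` and the remainder `w theta_j / (sum f + w
#' sum theta)`.
#'
#' @param seq Protein residue string, longer than `lambda` after stripping
#'   ambiguous `X` residues (stripped with a warning).
#' @param lambda Sequence-order correlation depth, integer in 1..10
#'   (default 4).
#' @param w Weight of the sequence-order factors (default 0.05).
#' @param scales Standardized property matrix as from [aa_property_scales]
#'   (20 rows, one column per scale).
#' @return Named numeric vector of length `20 + lambda`
#'   (`pseAA_A`..`pseAA_V`, `pseAA_theta1`..), summing to 1.
#' @export
pseudo_aa <- function(seq, lambda = 4, w = 0.05,
                      scales = aa_property_scales()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!is.numeric(lambda) || lambda < 1 || lambda > 10 ||
      lambda != round(lambda)) {
    stop("lambda must be an integer in 1..10")
  }
  if (!is.numeric(w) || w <= 0) stop("w must be > 0")
  chars <- strsplit(toupper(seq), "")[[1]]
  if (any(chars == "X")) {
    warning("ambiguous residue 'X' stripped before pseudo-AA computation")
    chars <- chars[chars != "X"]
  }
  bad <- setdiff(unique(chars), AA_CORE)
  if (length(bad)) stop("non-amino-acid symbol(s): ", paste(bad, collapse = ", "))
  L <- length(chars)
  if (L <= lambda) {
    stop(sprintf("sequence length %d must exceed lambda = %d", L, lambda))
  }
  f <- as.numeric(table(factor(chars, levels = AA_CORE))) / L
  prop <- scales[chars, , drop = FALSE]
  theta <- vapply(seq_len(lambda), function(j) {
    d <- prop[seq_len(L - j) + j, , drop = FALSE] -
      prop[seq_len(L - j), , drop = FALSE]
    mean(rowMeans(d^2))
  }, 0)
  denom <- sum(f) + w * sum(theta)
  out <- c(f / denom, w * theta / denom)
  names(out) <- c(paste0("pseAA_", AA_CORE),
                  paste0("pseAA_theta", seq_len(lambda)))
  out
}

#' Load a dinucleotide property table
#'
#' Reads the documented TSV dialect: a header line
#' `property<TAB>AA<TAB>AC ... <TAB>TT` followed by one row per property with
#' 16 dinucleotide values. The bundled table carries 12 literature-derived
#' conformational and thermodynamic properties; larger catalogs in the same
#' dialect can be supplied by the user.
#'
#' @param path Path to a property TSV; default is the bundled table.
#' @return A properties x 16 numeric matrix, columns named by dinucleotide.
#' @export
read_dinuc_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "dinuc_properties.tsv",
                        package = "seqfeatsim")
  }
  if (!file.exists(path)) stop("property table not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(colnames(df)[1], "property") ||
      !setequal(colnames(df)[-1], DINUCS)) {
    stop("property table must have columns: property, ",
         paste(DINUCS, collapse = ", "))
  }
  m <- as.matrix(df[, DINUCS])
  rownames(m) <- df$property
  if (any(!is.finite(m))) stop("property table contains non-finite values")
  m
}

#' Mean dinucleotide property values of one nucleotide sequence
#'
#' For each requested property, the mean value over all overlapping
#' dinucleotide windows. `U` is mapped to `T` for the (DNA-keyed) table
#' lookup; windows containing `N` are skipped.
#'
#' @param seq Nucleotide residue string of length >= 2.
#' @param table Property matrix from [read_dinuc_table].
#' @param properties Property names to compute (default: all in `table`).
#' @return Named numeric vector, one value per property.
#' @export
dinuc_features <- function(seq, table = read_dinuc_table(),
                           properties = rownames(table)) {
  stopifnot(is.character(seq), length(seq) == 1L)
  missing_p <- setdiff(properties, rownames(table))
  if (length(missing_p)) {
    stop("unknown property name(s): ", paste(missing_p, collapse = ", "))
  }
  chars <- strsplit(chartr("Uu", "Tt", toupper(seq)), "")[[1]]
  L <- length(chars)
  if (L < 2L) stop("sequence must have length >= 2")
  di <- paste0(chars[-L], chars[-1])
  di <- di[di %in% DINUCS]  # windows containing N are skipped
  if (length(di) == 0L) stop("no valid dinucleotide windows in sequence")
  out <- vapply(properties, function(p) mean(table[p, di]), 0)
  names(out) <- properties
  out
}

#' GC content of a nucleotide sequence
#'
#' `(G + C) / (A + C + G + T/U)`; `N` is excluded from the denominator.
#'
#' @param seq Nucleotide residue string.
#' @return Fraction in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(chartr("Uu", "Tt", toupper(seq)), "")[[1]]
  chars <- chars[chars %in% DNA_CORE]
  if (length(chars) == 0L) stop("no unambiguous nucleotides in sequence")
  mean(chars %in% c("G", "C"))
}

#' Specify a sequence feature extraction
#'
#' @param pseaa_lambda Pseudo-AA depth `lambda` (protein sets); `NULL` to skip.
#' @param pseaa_w Pseudo-AA weight `w`.
#' @param dinuc Character vector of dinucleotide property names (nucleotide
#'   sets); `NULL` to skip, `"all"` for every bundled/table property.
#' @param gc Include GC content (nucleotide sets)?
#' @param table Dinucleotide property matrix (default: bundled table).
#' @return An object of class `feature_spec`.
#' @export
feature_spec <- function(pseaa_lambda = NULL, pseaa_w = 0.05, dinuc = NULL,
                         gc = FALSE, table = NULL) {
  if (is.null(pseaa_lambda) && is.null(dinuc) && !isTRUE(gc)) {
    stop("empty feature specification: request pseudo-AA, dinucleotide ",
         "properties, or GC content")
  }
  if (!is.null(dinuc) || isTRUE(gc)) {
    if (is.null(table)) table <- read_dinuc_table()
    if (!is.null(dinuc) && identical(dinuc, "all")) dinuc <- rownames(table)
  }
  structure(list(pseaa_lambda = pseaa_lambda, pseaa_w = pseaa_w,
                 dinuc = dinuc, gc = isTRUE(gc), table = table),
            class = "feature_spec")
}

#' Extract a feature matrix from a sequence set
#'
#' One row per record, with named columns: `pseAA_*` for pseudo-AA components,
#' one column per dinucleotide property, and `gc`. Pseudo-AA features require
#' a protein set; dinucleotide/GC features require a nucleotide set.
#'
#' @param seqs A [seq_set].
#' @param spec A [feature_spec].
#' @return Numeric matrix, rows named by sequence identifier.
#' @export
extract_features <- function(seqs, spec) {
  stopifnot(inherits(seqs, "seq_set"), inherits(spec, "feature_spec"))
  is_protein <- seqs$alphabet == "protein"
  if (!is.null(spec$pseaa_lambda) && !is_protein) {
    stop("pseudo-AA features require a protein sequence set")
  }
  if ((length(spec$dinuc) || spec$gc) && is_protein) {
    stop("dinucleotide/GC features require a nucleotide sequence set")
  }
  rows <- lapply(seqs$sequences, function(s) {
    out <- numeric(0)
    if (!is.null(spec$pseaa_lambda)) {
      out <- c(out, pseudo_aa(s, lambda = spec$pseaa_lambda, w = spec$pseaa_w))
    }
    if (length(spec$dinuc)) {
      out <- c(out, dinuc_features(s, table = spec$table,
                                   properties = spec$dinuc))
    }
    if (spec$gc) out <- c(out, gc = gc_content(s))
    out
  })
  m <- do.call(rbind, rows)
  rownames(m) <- names(seqs$sequences)
  m
}
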