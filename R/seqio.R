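# Sequence and feature-table input/output with alphabet detection.

DNA_CORE <- c("A", "C", "G", "T")
RNA_CORE <- c("A", "C", "G", "U")
AA_CORE <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
             "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Core (unambiguous) symbols of an alphabet
#'
#' @param alphabet One of `"dna"`, `"rna"`, `"protein"`.
#' @return Character vector of 4 (nucleotide) or 20 (protein) symbols. The
#'   ambiguity codes `N` (nucleotide) and `X` (protein) are accepted on input
#'   but are not core symbols: they are excluded from composition estimates
#'   and never emitted by the simulators.
#' @export
alphabet_symbols <- function(alphabet) {
  switch(match.arg(alphabet, c("dna", "rna", "protein")),
    dna = DNA_CORE, rna = RNA_CORE, protein = AA_CORE)
}

ambiguity_symbol <- function(alphabet) {
  if (alphabet == "protein") "X" else "N"
}

#' Detect the alphabet of a set of residue strings
#'
#' Pools the symbols of all strings (after uppercasing) and classifies them as
#' DNA, RNA or protein. A set fitting several alphabets (e.g. `"ACG"`) is
#' resolved by the precedence DNA > RNA > protein, with a message noting the
#' ambiguity. RNA requires at least one `U`.
#'
#' @param residues Character vector of residue strings, at least one non-empty.
#' @return `"dna"`, `"rna"` or `"protein"`.
#' @export
detect_alphabet <- function(residues) {
  residues <- toupper(residues)
  syms <- unique(strsplit(paste(residues, collapse = ""), "")[[1]])
  if (length(syms) == 0L) stop("cannot detect alphabet: no residues supplied")
  fits_dna <- all(syms %in% c(DNA_CORE, "N"))
  fits_rna <- all(syms %in% c(RNA_CORE, "N"))
  fits_aa <- all(syms %in% c(AA_CORE, "X"))
  n_fit <- fits_dna + (fits_rna && "U" %in% syms) + fits_aa
  if (fits_dna) {
    if (n_fit > 1L || fits_aa) {
      message("alphabet ambiguous (symbols fit several alphabets); ",
              "using DNA by precedence")
    }
    return("dna")
  }
  if (fits_rna) {
    if (fits_aa) {
      message("alphabet ambiguous (symbols fit RNA and protein); ",
              "using RNA by precedence")
    }
    return("rna")
  }
  if (fits_aa) return("protein")
  bad <- setdiff(syms, unique(c(DNA_CORE, RNA_CORE, AA_CORE, "N", "X")))
  stop("symbols fit no supported alphabet: ",
       paste(shQuote(bad), collapse = ", "))
}

#' Construct a sequence set
#'
#' The package's sequence container: a named character vector of uppercase
#' residue strings plus a declared alphabet. All residues must belong to the
#' alphabet (core symbols plus its ambiguity code) and identifiers must be
#' unique.
#'
#' @param sequences Named character vector of residue strings (or unnamed, in
#'   which case ordinal identifiers `seq_0001`, ... are assigned).
#' @param alphabet `"dna"`, `"rna"`, `"protein"`, or `NULL` to detect.
#' @param descriptions Optional character vector of per-record descriptions.
#' @return An object of class `seq_set`.
#' @export
seq_set <- function(sequences, alphabet = NULL, descriptions = NULL) {
  ids <- names(sequences)
  sequences <- toupper(as.character(sequences))
  if (length(sequences) == 0L) stop("empty sequence set")
  if (any(!nzchar(sequences))) stop("empty residue string in sequence set")
  if (is.null(ids)) ids <- sprintf("seq_%04d", seq_along(sequences))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (is.null(alphabet)) alphabet <- detect_alphabet(sequences)
  allowed <- c(alphabet_symbols(alphabet), ambiguity_symbol(alphabet))
  for (i in seq_along(sequences)) {
    syms <- unique(strsplit(sequences[[i]], "")[[1]])
    bad <- setdiff(syms, allowed)
    if (length(bad)) {
      stop(sprintf("record '%s' contains symbol(s) %s outside the %s alphabet",
                   ids[[i]], paste(shQuote(bad), collapse = ", "),
                   toupper(alphabet)))
    }
  }
  names(sequences) <- ids
  structure(list(sequences = sequences, alphabet = alphabet,
                 descriptions = descriptions),
            class = "seq_set")
}

#' @export
print.seq_set <- function(x, ...) {
  lens <- nchar(x$sequences)
  cat(sprintf("seq_set: %d %s sequence(s), lengths %d-%d (median %g)\n",
              length(x$sequences), toupper(x$alphabet),
              min(lens), max(lens), stats::median(lens)))
  invisible(x)
}

#' @export
length.seq_set <- function(x) length(x$sequences)

#' Subset a sequence set
#' @param x A `seq_set`.
#' @param i Index vector.
#' @param ... Ignored.
#' @export
`[.seq_set` <- function(x, i, ...) {
  seq_set(x$sequences[i], alphabet = x$alphabet,
          descriptions = if (!is.null(x$descriptions)) x$descriptions[i])
}

#' Read sequences from FASTA or one-per-line text
#'
#' @param path Path to an existing file.
#' @param format `"fasta"`, `"lines"` or `"auto"` (sniffs a leading `>`).
#' @param alphabet Optional alphabet override; detected when `NULL`.
#' @return A [seq_set].
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "lines"),
                           alphabet = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("input file is empty: ", path)
  if (format == "auto") {
    format <- if (startsWith(trimws(lines[[1]]), ">")) "fasta" else "lines"
  }
  if (format == "fasta") {
    recs <- seqinr::read.fasta(path, as.string = TRUE, seqonly = FALSE,
                               forceDNAtolower = FALSE)
    seqs <- toupper(vapply(recs, function(r) as.character(r)[[1]], ""))
    ids <- vapply(recs, function(r) attr(r, "name"), "")
    desc <- vapply(recs, function(r) {
      a <- attr(r, "Annot")
      sub("^>\\S*\\s*", "", if (is.null(a)) "" else a)
    }, "")
    if (anyDuplicated(ids)) {
      stop("duplicate FASTA identifiers: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    }
    names(seqs) <- ids
  } else {
    seqs <- gsub("\\s", "", lines)
    names(seqs) <- sprintf("seq_%04d", seq_along(seqs))
    desc <- NULL
  }
  seq_set(seqs, alphabet = alphabet, descriptions = desc)
}

#' Write sequences to FASTA or one-per-line text
#'
#' FASTA output is wrapped at 70 columns.
#'
#' @param seqs A [seq_set].
#' @param path Output path.
#' @param format `"fasta"` or `"lines"`.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path, format = c("fasta", "lines")) {
  format <- match.arg(format)
  stopifnot(inherits(seqs, "seq_set"))
  if (format == "fasta") {
    seqinr::write.fasta(as.list(seqs$sequences), names = names(seqs$sequences),
                        file.out = path, nbchar = 70, as.string = TRUE)
  } else {
    writeLines(seqs$sequences, path)
  }
  invisible(path)
}

#' Read a numerical feature table
#'
#' Reads a delimited table of samples (rows) by named numerical features
#' (columns). Any non-numeric or missing cell is an error reporting the
#' offending row and column; ragged rows are rejected.
#'
#' @param path Path to the file.
#' @param delimiter Field separator (default tab).
#' @param header Does the first row carry feature names? Otherwise names
#'   `f1..fp` are generated.
#' @param row_ids Does the first column carry row identifiers?
#' @return A numeric matrix with `rownames` (row ids) and `colnames`
#'   (feature names).
#' @export
read_feature_table <- function(path, delimiter = "\t", header = TRUE,
                               row_ids = FALSE) {
  if (!file.exists(path)) stop("input file not found: ", path)
  raw <- utils::read.table(path, sep = delimiter, header = header,
                           colClasses = "character", check.names = FALSE,
                           fill = FALSE, blank.lines.skip = TRUE,
                           strip.white = TRUE)
  if (nrow(raw) == 0L || ncol(raw) == 0L) stop("feature table is empty: ", path)
  if (row_ids) {
    ids <- raw[[1]]
    raw <- raw[, -1, drop = FALSE]
  } else {
    ids <- sprintf("row_%04d", seq_len(nrow(raw)))
  }
  if (ncol(raw) < 1L) stop("feature table has no feature columns")
  fnames <- if (header) colnames(raw) else sprintf("f%d", seq_len(ncol(raw)))
  if (anyDuplicated(fnames)) {
    stop("duplicate feature names: ",
         paste(unique(fnames[duplicated(fnames)]), collapse = ", "))
  }
  vals <- suppressWarnings(
    vapply(raw, function(col) as.numeric(col), numeric(nrow(raw))))
  vals <- matrix(vals, nrow = nrow(raw))
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric or missing value at row %d, column '%s'",
                 bad[1, 1], fnames[bad[1, 2]]))
  }
  dimnames(vals) <- list(ids, fnames)
  vals
}

#' Write a numerical feature table
#'
#' @param x Numeric matrix (features in columns).
#' @param path Output path.
#' @param delimiter Field separator.
#' @param row_ids Write row identifiers as a leading `id` column?
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path, delimiter = "\t", row_ids = TRUE) {
  x <- as_feature_matrix(x)
  df <- as.data.frame(x, check.names = FALSE)
  if (row_ids) df <- cbind(id = rownames(x), df)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Coerce to a named numeric matrix; shared input validation.
as_feature_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("feature matrix must be a numeric matrix or data frame")
  }
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%d", seq_len(ncol(x)))
  if (is.null(rownames(x))) rownames(x) <- sprintf("row_%04d", seq_len(nrow(x)))
  if (any(!is.finite(x))) stop("feature matrix contains non-finite values")
  x
}
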