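# Profile hidden Markov model built from a multiple sequence alignment, and
# random sequence generation from it.
#
# Topology: a minimal match/insert/delete profile (Durbin-style) without
# flanking states. Columns with a gap fraction below 0.5 become match states;
# residues falling in non-match columns are emitted by the insert state of
# the preceding match position. Emission and transition probabilities are
# smoothed with a Laplace pseudocount. The alignment itself is an input: run
# any aligner you like beforehand and supply aligned FASTA.

#' Read a multiple sequence alignment from aligned FASTA
#'
#' @param path Aligned FASTA file; `-` marks gaps, all rows must have equal
#'   length and there must be at least 2 rows.
#' @param alphabet Optional alphabet override; detected from the degapped
#'   residues when `NULL`.
#' @return An object of class `msa` with `rows` (named, uppercase, gapped)
#'   and `alphabet`.
#' @export
read_msa <- function(path, alphabet = NULL) {
  if (!file.exists(path)) stop("MSA file not found: ", path)
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  rows <- toupper(vapply(recs, function(r) as.character(r)[[1]], ""))
  names(rows) <- vapply(recs, function(r) attr(r, "name"), "")
  msa(rows, alphabet = alphabet)
}

#' Construct an MSA object from gapped rows
#'
#' @param rows Character vector of equal-length gapped sequences.
#' @param alphabet Optional alphabet; detected from degapped residues if `NULL`.
#' @return An object of class `msa`.
#' @export
msa <- function(rows, alphabet = NULL) {
  rows <- toupper(rows)
  if (length(rows) < 2L) stop("an MSA needs at least 2 rows")
  if (length(unique(nchar(rows))) != 1L) {
    stop("MSA rows must all have the same (gapped) length")
  }
  degapped <- gsub("-", "", rows, fixed = TRUE)
  if (any(!nzchar(degapped))) stop("MSA contains an all-gap row")
  if (is.null(alphabet)) alphabet <- detect_alphabet(degapped)
  structure(list(rows = rows, alphabet = alphabet), class = "msa")
}

#' Build a profile HMM from a multiple sequence alignment
#'
#' Columns whose gap fraction is below 0.5 become match states. Match
#' emissions are pseudocount-smoothed column counts; insert states emit from
#' the overall residue background; transition probabilities are estimated from
#' the observed per-row state paths with the same pseudocount.
#'
#' @param msa An [msa] object.
#' @param pseudocount Positive smoothing constant (default 0.1).
#' @return An object of class `profile_hmm` with `M` (number of match
#'   states), `match_emissions` (`M` x symbols), `insert_emissions`
#'   (background row) and `transitions` (`(M+1)` x 3 x 3 array over
#'   from-states M/I/D and moves advance/insert/delete; position `k+1` holds
#'   the transitions taken at match position `k`, the advance move at the last
#'   position is the end transition).
#' @export
build_profile <- function(msa, pseudocount = 0.1) {
  stopifnot(inherits(msa, "msa"))
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    stop("pseudocount must be > 0")
  }
  syms <- alphabet_symbols(msa$alphabet)
  mat <- do.call(rbind, strsplit(msa$rows, ""))
  ncol_aln <- ncol(mat)
  gap_frac <- colMeans(mat == "-")
  is_match <- gap_frac < 0.5
  M <- sum(is_match)
  if (M == 0L) stop("MSA has no match columns (all columns mostly gaps)")
  match_idx <- integer(ncol_aln)
  match_idx[is_match] <- seq_len(M)

  # emission counts
  emit <- matrix(pseudocount, nrow = M, ncol = length(syms),
                 dimnames = list(NULL, syms))
  resid_all <- mat[mat != "-"]
  resid_all <- resid_all[resid_all %in% syms]
  bg <- (table(factor(resid_all, levels = syms)) + pseudocount)
  insert_emissions <- as.numeric(bg / sum(bg))
  names(insert_emissions) <- syms

  # transition counts: from in {M, I, D}, move in {advance, insert, delete}
  from_lv <- c("M", "I", "D")
  tcount <- array(0, dim = c(M + 1L, 3L, 3L),
                  dimnames = list(NULL, from_lv, c("advance", "insert",
                                                  "delete")))
  for (r in seq_len(nrow(mat))) {
    k <- 0L
    state <- "M"  # begin state behaves like M_0
    for (j in seq_len(ncol_aln)) {
      res <- mat[r, j]
      if (is_match[j]) {
        if (res != "-") {
          tcount[k + 1L, state, "advance"] <- tcount[k + 1L, state, "advance"] + 1
          k <- match_idx[j]
          state <- "M"
          if (res %in% syms) emit[k, res] <- emit[k, res] + 1
        } else {
          tcount[k + 1L, state, "delete"] <- tcount[k + 1L, state, "delete"] + 1
          k <- match_idx[j]
          state <- "D"
        }
      } else if (res != "-") {
        tcount[k + 1L, state, "insert"] <- tcount[k + 1L, state, "insert"] + 1
        state <- "I"
      }
    }
    # end transition, recorded as the advance move at position M
    tcount[M + 1L, state, "advance"] <- tcount[M + 1L, state, "advance"] + 1
  }

  # smooth and normalize; at the final position the delete move is impossible
  trans <- tcount + pseudocount
  trans[M + 1L, , "delete"] <- 0
  for (k in seq_len(M + 1L)) {
    for (f in 1:3) trans[k, f, ] <- trans[k, f, ] / sum(trans[k, f, ])
  }
  match_emissions <- emit / rowSums(emit)

  structure(list(M = M, alphabet = msa$alphabet,
                 match_emissions = match_emissions,
                 insert_emissions = insert_emissions,
                 transitions = trans),
            class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("profile_hmm (%s): %d match states\n", toupper(x$alphabet), x$M))
  invisible(x)
}

#' Consensus sequence of a profile HMM
#'
#' The modal emission residue of each match state.
#'
#' @param hmm A [build_profile] result.
#' @return A residue string of length `M`.
#' @export
profile_consensus <- function(hmm) {
  stopifnot(inherits(hmm, "profile_hmm"))
  syms <- colnames(hmm$match_emissions)
  paste(syms[apply(hmm$match_emissions, 1, which.max)], collapse = "")
}

#' Sample sequences from a profile HMM
#'
#' Stochastic traversal from begin to end, emitting from match and insert
#' states; output is ungapped. Consumes the R random number stream.
#'
#' @param hmm A [build_profile] result.
#' @param n Number of sequences (>= 1).
#' @param prefix Identifier prefix.
#' @return A [seq_set] of `n` records.
#' @export
sample_from_profile <- function(hmm, n, prefix = "hmm") {
  stopifnot(inherits(hmm, "profile_hmm"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  syms <- colnames(hmm$match_emissions)
  M <- hmm$M
  seqs <- character(n)
  for (i in seq_len(n)) {
    k <- 0L
    state <- "M"
    out <- character(0)
    repeat {
      move <- sample(3L, 1L, prob = hmm$transitions[k + 1L, state, ])
      if (move == 1L) {            # advance to next match (or end)
        if (k == M) break
        k <- k + 1L
        state <- "M"
        out <- c(out, sample(syms, 1L, prob = hmm$match_emissions[k, ]))
      } else if (move == 2L) {     # insert emission at position k
        state <- "I"
        out <- c(out, sample(syms, 1L, prob = hmm$insert_emissions))
      } else {                     # delete next match position
        if (k == M) break          # unreachable: delete mass is 0 at M
        k <- k + 1L
        state <- "D"
      }
    }
    seqs[i] <- paste(out, collapse = "")
  }
  empty <- !nzchar(seqs)
  if (any(empty)) seqs[empty] <- profile_consensus(hmm)  # all-delete path
  names(seqs) <- sprintf("%s_%06d", prefix, seq_len(n))
  seq_set(seqs, alphabet = hmm$alphabet)
}

#' Serialize a profile HMM to JSON text
#'
#' @param hmm A [build_profile] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(hmm, path) {
  stopifnot(inherits(hmm, "profile_hmm"))
  obj <- list(M = hmm$M, alphabet = hmm$alphabet,
              symbols = colnames(hmm$match_emissions),
              match_emissions = unname(as.matrix(hmm$match_emissions)),
              insert_emissions = as.numeric(hmm$insert_emissions),
              transitions = as.vector(hmm$transitions))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a profile HMM from its JSON serialization
#'
#' @param path Path written by [write_profile].
#' @return A `profile_hmm` object.
#' @export
read_profile <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  syms <- obj$symbols
  me <- matrix(unlist(obj$match_emissions), nrow = obj$M,
               dimnames = list(NULL, syms))
  ie <- as.numeric(obj$insert_emissions)
  names(ie) <- syms
  tr <- array(as.numeric(obj$transitions), dim = c(obj$M + 1L, 3L, 3L),
              dimnames = list(NULL, c("M", "I", "D"),
                              c("advance", "insert", "delete")))
  structure(list(M = obj$M, alphabet = obj$alphabet, match_emissions = me,
                 insert_emissions = ie, transitions = tr),
            class = "profile_hmm")
}
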