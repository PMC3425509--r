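# Global alignment of accepted inserts to the error-free extension product.
# Scoring follows the identity scheme of the original analysis: match +1,
# mismatch 0, gap open -10 (charged for the first gap position) and gap
# extend -2 for each additional position.  End gaps are scored like internal
# gaps (true global alignment), so abortive extensions are penalised and
# fail the acceptance filter rather than being silently trimmed.

#' Alignment parameters
#'
#' @param match,mismatch substitution scores.
#' @param gap_open cost of the first position of a gap (positive number,
#'   subtracted from the score).
#' @param gap_extend cost of each additional gap position.
#' @param min_insert_len minimum insert length accepted (inclusive).
#' @param min_score minimum alignment score accepted (exclusive: the score
#'   must be strictly greater).
#' @export
alignment_params <- function(match = 1, mismatch = 0, gap_open = 10,
                             gap_extend = 2, min_insert_len = 70L,
                             min_score = 60) {
  stopifnot(gap_open >= 0, gap_extend >= 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend,
                 min_insert_len = as.integer(min_insert_len),
                 min_score = min_score),
            class = "alignment_params")
}

substitution_matrix <- function(params) {
  letters5 <- c(DNA_BASES, "N")
  mat <- matrix(params$mismatch, 5, 5, dimnames = list(letters5, letters5))
  diag(mat)[1:4] <- params$match
  mat["N", ] <- 0; mat[, "N"] <- 0   # ambiguous bases score 0 everywhere
  mat
}

#' Global alignment against the product reference
#'
#' Needleman-Wunsch global alignment with affine gaps under the identity
#' scoring scheme.  A gap of length L costs `gap_open + gap_extend * (L-1)`.
#'
#' @param insert read insert sequence (query).
#' @param product_ref error-free extension product (subject).
#' @param params an [alignment_params()].
#' @return list with `score`, `aligned_insert` and `aligned_ref` (gapped
#'   strings of equal length).
#' @export
global_align <- function(insert, product_ref, params = alignment_params()) {
  stopifnot(nchar(insert) > 0, nchar(product_ref) > 0)
  if (nchar(insert) == nchar(product_ref) && insert == product_ref) {
    return(list(score = params$match * nchar(insert),
                aligned_insert = insert, aligned_ref = product_ref))
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(insert), Biostrings::DNAString(product_ref),
    type = "global", substitutionMatrix = substitution_matrix(params),
    gapOpening = params$gap_open - params$gap_extend,
    gapExtension = params$gap_extend)
  list(score = Biostrings::score(pa),
       aligned_insert = as.character(Biostrings::alignedPattern(pa)),
       aligned_ref = as.character(Biostrings::alignedSubject(pa)))
}

# Vectorised alignment of many inserts against one reference.  Returns the
# aligned insert in *reference coordinates*: a string of the reference
# length in which deletions appear as '-' and inserted bases are dropped
# (they are never counted towards any tally); `has_insertion` flags reads
# whose alignment contains an insertion.
#
# Inserts that have the reference length and are Hamming-close need no
# gapped alignment: with mismatch 0 and minimum gap cost 2 * gap_open, any
# gapped alignment of equal-length sequences scores at least 2 * gap_open
# below the all-match score, so the ungapped alignment is provably optimal
# whenever the Hamming distance is below that margin (ties prefer the
# mismatch reading over gaps).
align_batch <- function(inserts, product_ref, params = alignment_params()) {
  n <- length(inserts)
  L <- nchar(product_ref)
  score <- numeric(n)
  aligned <- character(n)
  has_ins <- logical(n)
  len <- nchar(inserts)
  margin <- 2 * params$gap_open / max(params$match - params$mismatch, 1e-9)
  hd <- rep(NA_integer_, n)
  same_len <- which(len == L)
  if (length(same_len)) {
    cm <- char_matrix(inserts[same_len], L)
    refc <- split_chars(product_ref)[[1L]]
    hd[same_len] <- rowSums(cm != matrix(refc, length(same_len), L,
                                         byrow = TRUE))
  }
  fast <- !is.na(hd) & hd < margin
  score[fast] <- params$match * (L - hd[fast]) + params$mismatch * hd[fast]
  aligned[fast] <- inserts[fast]
  slow <- which(!fast)
  if (length(slow)) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(inserts[slow]),
      Biostrings::DNAString(product_ref),
      type = "global", substitutionMatrix = substitution_matrix(params),
      gapOpening = params$gap_open - params$gap_extend,
      gapExtension = params$gap_extend)
    score[slow] <- Biostrings::score(pa)
    aligned[slow] <- as.character(Biostrings::aligned(pa))
    ins <- Biostrings::indel(Biostrings::subject(pa))
    has_ins[slow] <- lengths(ins) > 0
  }
  list(score = score, aligned = aligned, has_insertion = has_ins,
       insert_len = len)
}

#' Alignment acceptance rule
#'
#' Accept if and only if the insert is at least `min_insert_len` bases long
#' and the alignment score is strictly greater than `min_score`.
#'
#' @param insert_len insert length(s).
#' @param score alignment score(s).
#' @param params an [alignment_params()].
#' @return logical vector.
#' @export
accept_alignment <- function(insert_len, score, params = alignment_params()) {
  insert_len >= params$min_insert_len & score > params$min_score
}
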