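# Well barcodes.  Demultiplexing uses exact matching, so the set is built
# with a minimum pairwise Levenshtein distance (default 2): a single
# sequencing or synthesis error can never convert one barcode into another.

#' Generate a barcode set
#'
#' Greedily samples `n` distinct DNA `k`-mers whose pairwise Levenshtein
#' distances are all at least `min_dist`.  Candidates are drawn in a
#' seed-determined random order from the full 4^k space (enumerated when
#' small, sampled otherwise), so the result is deterministic given `seed`.
#'
#' @param n number of barcodes.
#' @param k barcode length in bases.
#' @param min_dist minimum pairwise Levenshtein distance.
#' @param seed integer seed.
#' @return an object of class `barcode_set`: list with `barcodes` (character
#'   vector) and `min_pairwise_levenshtein`.
#' @examples
#' bc <- generate_barcodes(8, 5, 2, seed = 1)
#' @export
generate_barcodes <- function(n, k, min_dist = 2L, seed = 1L) {
  stopifnot(n >= 1, k >= 1, min_dist >= 1)
  candidates <- with_seed(seed, {
    if (4^k <= 2^16) {
      all_kmers <- do.call(paste0, expand.grid(
        rep(list(DNA_BASES), k), stringsAsFactors = FALSE))
      sample(all_kmers)
    } else {
      m <- matrix(sample(DNA_BASES, 200L * n * k, replace = TRUE), ncol = k)
      unique(paste_rows(m))
    }
  })
  chosen <- character(0)
  for (cand in candidates) {
    if (length(chosen) == 0L || min(adist(cand, chosen)) >= min_dist) {
      chosen <- c(chosen, cand)
      if (length(chosen) == n) break
    }
  }
  if (length(chosen) < n) {
    stop(sprintf(paste0("cannot construct %d barcodes of length %d with ",
                        "pairwise Levenshtein distance >= %d: candidate ",
                        "space exhausted after %d accepted"),
                 n, k, min_dist, length(chosen)))
  }
  structure(list(barcodes = chosen,
                 min_pairwise_levenshtein = as.integer(min_dist)),
            class = "barcode_set")
}

#' @export
print.barcode_set <- function(x, ...) {
  cat(length(x$barcodes), "barcodes of length", nchar(x$barcodes[1]),
      "- min pairwise Levenshtein distance", x$min_pairwise_levenshtein, "\n")
  invisible(x)
}
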