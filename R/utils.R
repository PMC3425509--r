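#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef dchisq glm lm pchisq rbinom rgamma rgeom rmultinom
#'   runif sd setNames rpois binomial plogis qlogis vcov predict var cor
#'   chisq.test ppois dpois quantile
#' @importFrom utils adist head tail write.table read.delim packageVersion
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character vectors (A/C/G/T/N).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

complement_base <- function(b) {
  chartr("ACGTN", "TGCAN", b)
}

clip01 <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

#' Derive a per-well random seed from a plate seed
#'
#' Wells are seeded by a documented counter scheme so that any single well
#' of a plate can be regenerated in isolation: the i-th well uses
#' `(seed + 1000003 * i) mod (2^31 - 1)`.
#'
#' @param seed integer plate seed.
#' @param index 1-based well counter.
#' @return integer seed for the well's random stream.
#' @export
well_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(index)) %% 2147483647)
}

# Evaluate `expr` under a local RNG stream, restoring global RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

split_chars <- function(x) strsplit(x, "", fixed = TRUE)

# character matrix (n x width) from equal-length strings
char_matrix <- function(x, width) {
  matrix(unlist(split_chars(x), use.names = FALSE),
         nrow = length(x), ncol = width, byrow = TRUE)
}

paste_rows <- function(m) {
  do.call(paste0, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
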