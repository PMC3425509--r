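# Misincorporation tallies.  Aligned columns where both sides are bases
# increment the total-event count at that template position and the
# (template base x incorporated dNTP) transition count, and the error count
# on mismatch; columns containing a gap or an ambiguous base, and inserted
# read bases (which consume no template position), contribute to neither
# numerator nor denominator.  Positions are 1-based along the template
# extension region in extension order; the incorporated dNTP is the read
# base and the template base is the template-strand base (the complement of
# the product-reference base).

new_tally <- function(L, template) {
  tb <- template$template_ext_order[seq_len(L)]
  structure(list(
    per_position = data.frame(position = seq_len(L), template_base = tb,
                              n_err = 0, n_tot = 0),
    transitions = matrix(0, 4, 4, dimnames = list(template = DNA_BASES,
                                                  incorporated = DNA_BASES)),
    reads_used = 0L, reads_rejected_by_alignment = 0L,
    template = template$name), class = "mis_tally")
}

#' Tally misincorporations from accepted alignments
#'
#' @param aligned accepted alignments in reference coordinates: strings of
#'   the reference length with `-` marking deleted positions (the
#'   `aligned` component of the internal batch aligner; inserted bases are
#'   already excluded since they consume no template position).
#' @param template the [template_spec()] the reference belongs to.
#' @param reads_rejected number of reads that failed the alignment filters
#'   (recorded in the tally for bookkeeping).
#' @return object of class `mis_tally` with fields `per_position`
#'   (data.frame `position`, `template_base`, `n_err`, `n_tot`),
#'   `transitions` (4x4 count matrix, template base x incorporated dNTP;
#'   correct incorporations sit in the Watson-Crick cells), `reads_used`
#'   and `reads_rejected_by_alignment`.
#' @export
tally_alignments <- function(aligned, template, reads_rejected = 0L) {
  L <- template$ext_len
  tal <- new_tally(L, template)
  tal$reads_rejected_by_alignment <- as.integer(reads_rejected)
  n <- length(aligned)
  tal$reads_used <- n
  if (n == 0L) return(tal)
  if (any(nchar(aligned) != L)) {
    stop("alignment references positions outside the template")
  }
  refc <- split_chars(template$product_ref)[[1L]]
  tb_code <- match(template$template_ext_order, DNA_BASES)

  cm <- char_matrix(aligned, L)
  code <- match(cm, DNA_BASES)            # NA for '-' and 'N'
  valid <- !is.na(code)
  dim(valid) <- dim(cm)
  refm <- matrix(refc, n, L, byrow = TRUE)
  mism <- (cm != refm) & valid
  tal$per_position$n_err <- colSums(mism)
  tal$per_position$n_tot <- colSums(valid)
  tbm <- matrix(tb_code, n, L, byrow = TRUE)
  tal$transitions[] <- matrix(tabulate((tbm[valid] - 1L) * 4L + code[valid],
                                       nbins = 16L), 4, 4, byrow = TRUE)
  tal
}

#' Align a well's inserts and tally misincorporations
#'
#' Applies the length pre-filter, aligns remaining inserts to the product
#' reference, applies [accept_alignment()] and tallies the accepted reads.
#'
#' @param inserts character vector of insert sequences.
#' @param template a [template_spec()].
#' @param params an [alignment_params()].
#' @param keep_error_matrix if `TRUE`, also return the binary error matrix
#'   over the first `emat_cols` template positions for indel-free reads
#'   (see [error_matrix()]).
#' @param emat_cols number of leading template positions for the error
#'   matrix.
#' @return list with `tally` (a `mis_tally`) and, when requested,
#'   `error_matrix`.
#' @export
quantify_well <- function(inserts, template, params = alignment_params(),
                          keep_error_matrix = FALSE, emat_cols = 70L) {
  len <- nchar(inserts)
  long_enough <- len >= params$min_insert_len
  batch <- align_batch(inserts[long_enough], template$product_ref, params)
  acc <- accept_alignment(batch$insert_len, batch$score, params)
  rejected <- sum(!long_enough) + sum(!acc)
  tal <- tally_alignments(batch$aligned[acc], template,
                          reads_rejected = rejected)
  out <- list(tally = tal)
  if (keep_error_matrix) {
    out$error_matrix <- error_matrix(batch$aligned[acc], template,
                                     has_insertion = batch$has_insertion[acc],
                                     n_cols = emat_cols)
  }
  out
}

#' Combine tallies by summing counts
#'
#' @param tallies list of `mis_tally` objects over the same template.
#' @return a single `mis_tally`.
#' @export
combine_tallies <- function(tallies) {
  stopifnot(length(tallies) >= 1)
  out <- tallies[[1]]
  for (t in tallies[-1]) {
    stopifnot(nrow(t$per_position) == nrow(out$per_position))
    out$per_position$n_err <- out$per_position$n_err + t$per_position$n_err
    out$per_position$n_tot <- out$per_position$n_tot + t$per_position$n_tot
    out$transitions <- out$transitions + t$transitions
    out$reads_used <- out$reads_used + t$reads_used
    out$reads_rejected_by_alignment <-
      out$reads_rejected_by_alignment + t$reads_rejected_by_alignment
  }
  out
}

#' Misincorporation rates from a tally
#'
#' Rates are ratios of misincorporation counts to total counted events.
#' The mean misincorporation rate is the unweighted average of the four
#' per-template-base rates; undefined rates (zero denominator) are flagged
#' `NA` and excluded from the mean.
#'
#' @param tally a `mis_tally`.
#' @return list with `per_position` (data.frame adding `rate`), `per_base`
#'   (data.frame `template_base`, `n_err`, `n_tot`, `rate`) and `mean_rate`.
#' @export
misincorporation_rates <- function(tally) {
  pp <- tally$per_position
  pp$rate <- ifelse(pp$n_tot > 0, pp$n_err / pp$n_tot, NA_real_)
  pb <- data.frame(template_base = DNA_BASES,
                   n_err = vapply(DNA_BASES, function(b)
                     sum(pp$n_err[pp$template_base == b]), numeric(1)),
                   n_tot = vapply(DNA_BASES, function(b)
                     sum(pp$n_tot[pp$template_base == b]), numeric(1)))
  pb$rate <- ifelse(pb$n_tot > 0, pb$n_err / pb$n_tot, NA_real_)
  rownames(pb) <- NULL
  list(per_position = pp, per_base = pb,
       mean_rate = mean(pb$rate, na.rm = TRUE))
}

#' Normalised wrong-dNTP transition distributions
#'
#' For each template base, the counts of the three wrong incoming dNTPs are
#' normalised to sum to 1.  The Watson-Crick (correct) cell is `NA`; rows
#' with zero misincorporations are all-`NA` (omitted).
#'
#' @param tally a `mis_tally`.
#' @return 4x4 matrix (template base x incorporated dNTP) of wrong-dNTP
#'   fractions.
#' @export
transition_matrix <- function(tally) {
  tm <- matrix(NA_real_, 4, 4, dimnames = dimnames(tally$transitions))
  for (b in DNA_BASES) {
    wrong <- setdiff(DNA_BASES, complement_base(b))
    cnt <- tally$transitions[b, wrong]
    if (sum(cnt) > 0) tm[b, wrong] <- cnt / sum(cnt)
  }
  tm
}

#' Replicate mean and standard error
#'
#' Duplicate wells with nominally equal conditions are analysed
#' independently; this summarises them as the mean and the standard error
#' of the replicate means (`sd/sqrt(n)`; `NA`-flagged when `n = 1`).
#'
#' @param values numeric vector of per-well estimates.
#' @param groups grouping factor (condition labels), same length.
#' @return data.frame with `group`, `mean`, `sem`, `n_replicates`.
#' @export
replicate_stats <- function(values, groups) {
  groups <- factor(groups, levels = unique(groups))
  agg <- tapply(values, groups, function(v) {
    v <- v[!is.na(v)]
    c(mean = mean(v), sem = if (length(v) > 1) sd(v) / sqrt(length(v))
      else NA_real_, n = length(v))
  })
  out <- data.frame(group = names(agg),
                    mean = vapply(agg, `[[`, numeric(1), "mean"),
                    sem = vapply(agg, `[[`, numeric(1), "sem"),
                    n_replicates = vapply(agg, `[[`, numeric(1), "n"))
  rownames(out) <- NULL
  out
}

#' Experimental noise floor from high-fidelity control wells
#'
#' Two flavours: `mean_floor` is the mean of the four per-template-base
#' control misincorporation rates plus the standard error of that mean
#' (taken across template bases); `spatial_floor` is the maximum over
#' template positions of the across-well mean rate plus its standard error.
#'
#' @param control_tallies list of `mis_tally` objects from control wells.
#' @return list with `mean_floor` and `spatial_floor`.
#' @export
noise_floor <- function(control_tallies) {
  stopifnot(length(control_tallies) >= 1)
  pooled <- misincorporation_rates(combine_tallies(control_tallies))
  br <- pooled$per_base$rate
  br <- br[!is.na(br)]
  mean_floor <- mean(br) + if (length(br) > 1)
    sd(br) / sqrt(length(br)) else 0
  pr <- vapply(control_tallies, function(t)
    misincorporation_rates(t)$per_position$rate,
    numeric(nrow(control_tallies[[1]]$per_position)))
  pr <- matrix(pr, ncol = length(control_tallies))
  pos_mean <- rowMeans(pr, na.rm = TRUE)
  pos_sem <- if (ncol(pr) > 1)
    apply(pr, 1, function(v) sd(v[!is.na(v)]) / sqrt(sum(!is.na(v))))
  else rep(0, nrow(pr))
  pos_sem[is.na(pos_sem)] <- 0
  list(mean_floor = mean_floor,
       spatial_floor = max(pos_mean + pos_sem, na.rm = TRUE))
}

#' @export
print.mis_tally <- function(x, ...) {
  cat("Misincorporation tally (", x$template, "): ", x$reads_used,
      " reads used, ", x$reads_rejected_by_alignment,
      " rejected by alignment\n", sep = "")
  cat("  total errors:", sum(x$per_position$n_err),
      "over", sum(x$per_position$n_tot), "events\n")
  invisible(x)
}
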