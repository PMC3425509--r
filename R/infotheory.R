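# Shannon information gain per base about a binary cation state.  With
# equal priors p(H) = p(L) = 1/2 there is one bit of missing information;
# observing whether a given template position was miscopied updates the
# posterior by Bayes' rule, and the gain is one minus the expected
# posterior entropy.

xlog2x <- function(p) ifelse(p > 0, p * log2(p), 0)   # 0*log2(0) == 0

#' Information gain of one template position
#'
#' @param p_I_given_H,p_I_given_L misincorporation probability at the high
#'   and low cation state.
#' @param prior_H,prior_L prior state probabilities (must sum to 1).
#' @return object of class `info_result`: list with `gain_bits`, `h_exp`
#'   (expected posterior entropy) and the intermediate quantities `p_I`,
#'   `p_H_given_I`, `p_L_given_I`, `p_H_given_C`, `p_L_given_C`,
#'   `H_incorrect`, `H_correct`.
#' @examples
#' info_gain(0.07, 0.0014)$gain_bits
#' @export
info_gain <- function(p_I_given_H, p_I_given_L,
                      prior_H = 0.5, prior_L = 0.5) {
  stopifnot(p_I_given_H >= 0, p_I_given_H <= 1,
            p_I_given_L >= 0, p_I_given_L <= 1,
            abs(prior_H + prior_L - 1) < 1e-12, prior_H >= 0, prior_L >= 0)
  p_I <- p_I_given_H * prior_H + p_I_given_L * prior_L
  p_H_given_I <- if (p_I > 0) p_I_given_H * prior_H / p_I else prior_H
  p_L_given_I <- 1 - p_H_given_I
  p_C <- 1 - p_I
  p_H_given_C <- if (p_C > 0) (1 - p_I_given_H) * prior_H / p_C else prior_H
  p_L_given_C <- 1 - p_H_given_C
  H_incorrect <- -xlog2x(p_H_given_I) - xlog2x(p_L_given_I)
  H_correct <- -xlog2x(p_H_given_C) - xlog2x(p_L_given_C)
  h_exp <- p_I * H_incorrect + p_C * H_correct
  prior_entropy <- -xlog2x(prior_H) - xlog2x(prior_L)
  structure(list(gain_bits = prior_entropy - h_exp, h_exp = h_exp,
                 p_I = p_I, p_H_given_I = p_H_given_I,
                 p_L_given_I = p_L_given_I, p_H_given_C = p_H_given_C,
                 p_L_given_C = p_L_given_C, H_incorrect = H_incorrect,
                 H_correct = H_correct),
            class = "info_result")
}

#' Per-position information-gain profile
#'
#' Applies [info_gain()] position by position to two per-position rate
#' tables measured at the high and low cation state.
#'
#' @param rates_high,rates_low data.frames with `position` and `rate`
#'   (e.g. `misincorporation_rates(tally)$per_position`).
#' @param prior_H,prior_L priors passed to [info_gain()].
#' @return list with `profile` (data.frame `position`, `gain_bits`; rows
#'   with undefined rates are flagged `NA` and skipped for the summary),
#'   `max_gain_bits` and `max_position`.
#' @export
info_profile <- function(rates_high, rates_low, prior_H = 0.5, prior_L = 0.5) {
  m <- merge(rates_high[, c("position", "rate")],
             rates_low[, c("position", "rate")],
             by = "position", suffixes = c("_high", "_low"))
  m <- m[order(m$position), ]
  gain <- mapply(function(ph, pl) {
    if (is.na(ph) || is.na(pl)) NA_real_
    else info_gain(ph, pl, prior_H, prior_L)$gain_bits
  }, m$rate_high, m$rate_low)
  prof <- data.frame(position = m$position, gain_bits = gain)
  ok <- which(!is.na(gain))
  list(profile = prof,
       max_gain_bits = if (length(ok)) max(gain[ok]) else NA_real_,
       max_position = if (length(ok)) prof$position[ok][which.max(gain[ok])]
       else NA_integer_)
}

#' Recording capacity of a template
#'
#' Total bytes recordable at a given per-base information gain, using
#' decimal megabyte conventions (1 MB = 1e6 bytes).
#'
#' @param bits_per_base information gain per base in [0, 1].
#' @param template_length number of bases written.
#' @return list with `bytes` and `megabytes`.
#' @export
capacity_bytes <- function(bits_per_base, template_length) {
  stopifnot(bits_per_base >= 0, bits_per_base <= 1, template_length > 0)
  bytes <- bits_per_base * template_length / 8
  list(bytes = bytes, megabytes = bytes / 1e6)
}

#' @export
print.info_result <- function(x, ...) {
  cat(sprintf("Information gain: %.4g bits (expected posterior entropy %.4g)\n",
              x$gain_bits, x$h_exp))
  invisible(x)
}
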