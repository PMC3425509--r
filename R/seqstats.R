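# Statistical layer on the error matrix: lag-one excess errors, Poisson
# overdispersion of per-read error totals, and a binomial GLM over sequence
# and secondary-structure features with cross-template prediction.

#' Binary error matrix from accepted alignments
#'
#' Rows are accepted reads whose alignments contain no insertion and no
#' deletion over the first `n_cols` template positions; columns are those
#' positions (extension order).  Entries are 1 where the read base
#' mismatches the reference.
#'
#' @param aligned accepted alignments in reference coordinates (strings of
#'   the reference length, `-` marking deletions), as produced by the
#'   internal batch aligner.
#' @param template a [template_spec()].
#' @param has_insertion logical vector flagging reads whose alignments
#'   contain insertions (excluded from the matrix).
#' @param n_cols number of leading template positions (default 70).
#' @return binary integer matrix (class `error_matrix`), with attribute
#'   `template_base` giving the per-column template bases.
#' @export
error_matrix <- function(aligned, template,
                         has_insertion = logical(length(aligned)),
                         n_cols = 70L) {
  L <- template$ext_len
  stopifnot(n_cols <= L, length(has_insertion) == length(aligned))
  refc <- split_chars(template$product_ref)[[1L]]
  head_part <- substr(aligned, 1L, n_cols)
  keep <- which(!has_insertion & !grepl("-", head_part, fixed = TRUE) &
                  nchar(aligned) == L)
  m <- if (length(keep)) {
    cm <- char_matrix(head_part[keep], n_cols)
    refm <- matrix(refc[seq_len(n_cols)], length(keep), n_cols, byrow = TRUE)
    (cm != refm) * 1L
  } else matrix(integer(0), 0, n_cols)
  dimnames(m) <- NULL
  structure(m, template_base = template$template_ext_order[seq_len(n_cols)],
            class = c("error_matrix", class(m)))
}

#' Lag-one excess errors
#'
#' For each adjacent position pair (p, p+1) the observed joint error
#' frequency is compared with the expectation under independence formed
#' from the two positions' own rates, `(n_p / N_t) * (n_{p+1} / N_t)` --
#' the position-specific product corrects for error-rate structure within
#' the template itself.  The excess is the mean difference over pairs,
#' reported in percent per base, with a seeded bootstrap (resampling reads)
#' supplying the standard error.
#'
#' @param emat an [error_matrix()] (reads x positions, binary).
#' @param n_boot bootstrap resamples (0 disables the SE).
#' @param seed bootstrap seed.
#' @return list with `excess_pct`, `se_pct`, `per_pair` (data.frame with
#'   observed and expected joint frequencies per adjacent pair) and `n_reads`.
#' @export
lag_one_excess <- function(emat, n_boot = 1000L, seed = 1L) {
  n <- nrow(emat)
  if (n < 2) stop("lag-one excess needs at least 2 reads")
  L <- ncol(emat)
  joint <- colSums(emat[, -L, drop = FALSE] * emat[, -1L, drop = FALSE])
  rate <- colSums(emat) / n
  obs <- joint / n
  expd <- rate[-L] * rate[-1L]
  excess <- mean(obs - expd)
  se <- NA_real_
  if (n_boot > 0) {
    se <- with_seed(seed, {
      pair_ind <- emat[, -L, drop = FALSE] * emat[, -1L, drop = FALSE]
      boots <- numeric(n_boot)
      chunk <- 250L
      done <- 0L
      while (done < n_boot) {
        b <- min(chunk, n_boot - done)
        w <- rmultinom(b, n, rep(1 / n, n))       # n x b resample weights
        cs <- crossprod(w, emat) / n              # b x L column means
        js <- crossprod(w, pair_ind) / n          # b x (L-1) joint means
        boots[done + seq_len(b)] <-
          rowMeans(js - cs[, -L, drop = FALSE] * cs[, -1L, drop = FALSE])
        done <- done + b
      }
      sd(boots)
    })
  }
  list(excess_pct = 100 * excess, se_pct = 100 * se,
       per_pair = data.frame(pair = seq_len(L - 1L), observed = obs,
                             expected = expd),
       n_reads = n)
}

#' Poisson dispersion test on per-read error totals
#'
#' If every molecule misincorporated with identical statistics, the total
#' number of errors per read would be Poisson.  This computes the
#' variance/mean dispersion index of the per-read totals and a chi-square
#' goodness-of-fit test against Poisson with the sample mean as rate,
#' pooling count bins so that every expected count is at least
#' `min_expected`.
#'
#' @param emat an [error_matrix()], or a vector of per-read totals.
#' @param min_expected minimum expected count per chi-square bin.
#' @param min_reads minimum number of reads for the chi-square
#'   approximation.
#' @return list with `mean`, `variance`, `dispersion_index`, `chisq`, `df`,
#'   `p_value`, `n_reads`; degenerate all-zero input is flagged with
#'   `p_value = NA`.
#' @export
dispersion_test <- function(emat, min_expected = 5, min_reads = 30L) {
  totals <- if (is.matrix(emat)) rowSums(emat) else as.numeric(emat)
  n <- length(totals)
  if (n < min_reads) stop("dispersion test needs at least ", min_reads,
                          " reads")
  m <- mean(totals)
  v <- var(totals)
  if (m == 0) {
    return(list(mean = 0, variance = 0, dispersion_index = NA_real_,
                chisq = NA_real_, df = NA_integer_, p_value = NA_real_,
                n_reads = n, flag = "no errors observed"))
  }
  kmax <- max(totals)
  obs <- tabulate(totals + 1L, nbins = kmax + 1L)      # counts of 0..kmax
  expd <- c(dpois(0:(kmax - 1L), m), 1 - ppois(kmax - 1L, m)) * n
  # pool from the right tail until all expected counts are adequate
  while (length(expd) > 2 && expd[length(expd)] < min_expected) {
    k <- length(expd)
    expd[k - 1L] <- expd[k - 1L] + expd[k]
    obs[k - 1L] <- obs[k - 1L] + obs[k]
    expd <- expd[-k]; obs <- obs[-k]
  }
  # pool any remaining sparse interior bins into their left neighbour
  while (length(expd) > 2 && any(expd < min_expected)) {
    k <- which(expd < min_expected)[1L]
    j <- if (k == 1L) 2L else k - 1L
    expd[j] <- expd[j] + expd[k]; obs[j] <- obs[j] + obs[k]
    expd <- expd[-k]; obs <- obs[-k]
  }
  stat <- sum((obs - expd)^2 / expd)
  df <- length(expd) - 2L                # one for totals, one for the mean
  if (df < 1L) df <- 1L
  list(mean = m, variance = v, dispersion_index = v / m,
       chisq = stat, df = df, p_value = pchisq(stat, df, lower.tail = FALSE),
       n_reads = n)
}

#' GLM design over sequence and structure features
#'
#' One modelled row per template position 4..(n_cols-3) (the first and last
#' three positions are dropped so that the +/-3 structure window is always
#' defined): three template-base indicators (`base_C`, `base_G`, `base_T`;
#' template A is absorbed in the intercept), a continuous `position`
#' feature, and the structure profile at offsets -3..+3 (`s_m3` .. `s_p3`).
#'
#' @param template a [template_spec()].
#' @param profile structure profile: data.frame with `position` and `s`
#'   covering at least positions 1..n_cols (e.g. [toy_structure_profile()]).
#' @param n_cols length of the modelled alignment window (default 70).
#' @return data.frame of features with attribute `positions` (the modelled
#'   template positions).
#' @export
build_design <- function(template, profile, n_cols = 70L) {
  s <- profile$s[order(profile$position)]
  if (length(s) < n_cols) stop("structure profile (", length(s),
                               " positions) does not cover 1..", n_cols)
  if (any(s < 0 | s > 1, na.rm = TRUE)) stop("structure values must be in [0,1]")
  pos <- 4L:(n_cols - 3L)
  tb <- attr_template_bases(template, n_cols)[pos]
  X <- data.frame(
    base_C = as.integer(tb == "C"),
    base_G = as.integer(tb == "G"),
    base_T = as.integer(tb == "T"),
    position = pos
  )
  for (k in -3:3) {
    nm <- paste0("s_", ifelse(k < 0, "m", "p"), abs(k))
    X[[sub("p0", "0", nm)]] <- s[pos + k]
  }
  attr(X, "positions") <- pos
  X
}

attr_template_bases <- function(template, n_cols) {
  template$template_ext_order[seq_len(n_cols)]
}

#' Fit the binomial misincorporation GLM
#'
#' Logistic-link binomial GLM fitted by iteratively reweighted least
#' squares (convergence tolerance 1e-8).  Outcomes may be per-row binary
#' indicators or aggregated successes/totals per design row (identical
#' likelihood).
#'
#' @param design feature data.frame from [build_design()] (or any numeric
#'   design).
#' @param errors per-row error counts (or binary outcomes).
#' @param totals per-row totals (defaults to 1, i.e. Bernoulli rows).
#' @return object of class `glm_fit`: list with `coefficients` (data.frame
#'   `term`, `estimate`, `se`), `fitted_rates`, the underlying `glm` object
#'   and `positions` when present on the design.
#' @export
fit_glm <- function(design, errors, totals = NULL) {
  X <- as.data.frame(design)
  if (is.null(totals)) totals <- rep(1L, length(errors))
  stopifnot(length(errors) == nrow(X), length(totals) == nrow(X),
            all(errors >= 0), all(errors <= totals))
  dat <- cbind(X, .err = errors, .tot = totals)
  fml <- stats::as.formula(paste("cbind(.err, .tot - .err) ~",
                                 paste(names(X), collapse = " + ")))
  fit <- glm(fml, data = dat, family = binomial(),
             control = list(epsilon = 1e-8, maxit = 50))
  if (!fit$converged) stop("GLM did not converge after 50 IRLS iterations")
  sm <- summary(fit)$coefficients
  structure(list(
    coefficients = data.frame(term = rownames(sm), estimate = sm[, 1],
                              se = sm[, 2], row.names = NULL),
    fitted_rates = unname(fit$fitted.values),
    glm = fit,
    positions = attr(design, "positions")
  ), class = "glm_fit")
}

#' Predict per-position rates and score with R-squared
#'
#' Applies a fitted GLM's weights to a (possibly different template's)
#' design and reports the squared Pearson correlation between predicted and
#' observed per-position rates over the modelled positions — the
#' cross-template transferability score.
#'
#' @param fit a [fit_glm()] result.
#' @param design design to score on.
#' @param errors,totals observed per-row counts on that design.
#' @return list with `r_squared`, `predicted` and `observed` per-row rates.
#' @export
glm_predict_r2 <- function(fit, design, errors, totals = NULL) {
  X <- as.data.frame(design)
  if (is.null(totals)) totals <- rep(1L, length(errors))
  beta <- fit$coefficients$estimate
  Xm <- cbind(1, as.matrix(X))
  pred <- plogis(as.vector(Xm %*% beta))
  obs <- errors / totals
  list(r_squared = suppressWarnings(cor(pred, obs))^2,
       predicted = pred, observed = obs)
}

#' @export
print.glm_fit <- function(x, ...) {
  cat("Binomial GLM fit:", nrow(x$coefficients), "coefficients\n")
  print(x$coefficients, digits = 3)
  invisible(x)
}
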