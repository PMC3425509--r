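# Transfer functions: rate-versus-concentration series summarised as gains
# (%/mM, ordinary least squares), fold changes relative to the lowest
# concentration of the titration, Ca2+ endpoint responses, and the classic
# blue/white colony-assay error rate.

#' Quantify every well of a demultiplexed plate
#'
#' @param demux result of [filter_and_demux()].
#' @param plate the [plate_design()] that generated the reads.
#' @param template a [template_spec()].
#' @param params an [alignment_params()].
#' @return list with `tallies` (named list of per-well `mis_tally`) and
#'   `well_rates` (data.frame: well metadata, per-base rates `rate_A` ..
#'   `rate_T`, `mean_rate`, `reads_used`).
#' @export
quantify_plate <- function(demux, plate, template = bundled_template("original"),
                           params = alignment_params()) {
  wells <- plate$wells
  tallies <- vector("list", nrow(wells))
  names(tallies) <- wells$well_id
  rows <- vector("list", nrow(wells))
  for (i in seq_len(nrow(wells))) {
    wid <- wells$well_id[i]
    q <- quantify_well(demux$wells[[wid]] %||% character(0), template, params)
    tallies[[wid]] <- q$tally
    r <- misincorporation_rates(q$tally)
    pb <- setNames(r$per_base$rate, paste0("rate_", r$per_base$template_base))
    rows[[i]] <- cbind(wells[i, , drop = FALSE], as.list(pb),
                       mean_rate = r$mean_rate,
                       reads_used = q$tally$reads_used)
  }
  well_rates <- do.call(rbind, rows)
  rownames(well_rates) <- NULL
  list(tallies = tallies, well_rates = well_rates)
}

#' Replicate-averaged titration series
#'
#' Averages per-well rates over duplicate wells of each condition and
#' orders conditions by the varied cation.
#'
#' @param well_rates the `well_rates` data.frame from [quantify_plate()].
#' @param varied which cation is titrated: `"mn"`, `"mg"` or `"ca"`.
#' @return object of class `titration_series`: data.frame with `conc_uM`,
#'   `conc_mM`, replicate mean and SEM of the mean rate (`rate`, `sem`,
#'   `n_replicates`) and of each per-base rate (`rate_A` .. `rate_T`).
#' @export
titration_series <- function(well_rates, varied = c("mn", "mg", "ca")) {
  varied <- match.arg(varied)
  conc_col <- paste0(varied, "_uM")
  grp <- well_rates$replicate_group
  agg <- replicate_stats(well_rates$mean_rate, grp)
  conc <- tapply(well_rates[[conc_col]], factor(grp, levels = unique(grp)),
                 unique)
  if (any(vapply(conc, length, integer(1)) != 1)) {
    stop("replicate groups mix different ", varied, " concentrations")
  }
  out <- data.frame(conc_uM = as.numeric(conc), conc_mM = as.numeric(conc) / 1000,
                    rate = agg$mean, sem = agg$sem,
                    n_replicates = agg$n_replicates)
  for (b in DNA_BASES) {
    out[[paste0("rate_", b)]] <-
      replicate_stats(well_rates[[paste0("rate_", b)]], grp)$mean
  }
  out <- out[order(out$conc_uM), ]
  rownames(out) <- NULL
  if (any(duplicated(out$conc_uM))) {
    stop("varied cation must be strictly increasing across conditions")
  }
  class(out) <- c("titration_series", "data.frame")
  out
}

#' Transfer-function gain and fold change
#'
#' The gain is the ordinary least-squares slope of the replicate-mean
#' misincorporation rate, expressed in percent, against the varied cation
#' concentration in mM.  The fold change is the rate at the highest
#' concentration divided by the rate at the lowest concentration of the
#' titration.
#'
#' @param series a [titration_series()] (or data.frame with `conc_mM` and
#'   `rate` as fractions).
#' @param rate_col column to fit (default the mean rate; use e.g.
#'   `"rate_T"` for a template-base-specific gain).
#' @return list with `gain` (%/mM), `gain_se`, `fold_change`, `n_points`.
#' @export
fit_gain <- function(series, rate_col = "rate") {
  y <- series[[rate_col]]
  x <- series$conc_mM
  keep <- !is.na(y) & !is.na(x)
  if (sum(keep) < 2) stop("fit_gain needs at least 2 points with defined rates")
  fit <- lm(I(100 * y[keep]) ~ x[keep])
  lo <- y[keep][which.min(x[keep])]
  hi <- y[keep][which.max(x[keep])]
  # two-point and perfectly collinear series fit exactly; summary.lm warns
  se <- suppressWarnings(unname(sqrt(diag(vcov(fit)))[2]))
  list(gain = unname(coef(fit)[2]),
       gain_se = se,
       fold_change = if (lo > 0) hi / lo else NA_real_,
       n_points = sum(keep))
}

#' Ca2+ endpoint response
#'
#' Fold change (and percent change) of the rate between the lowest and
#' highest Ca2+ concentrations of a titration at fixed Mn2+/Mg2+ background.
#'
#' @param series a [titration_series()] varied in Ca2+.
#' @param rate_col rate column to compare.
#' @return list with `fold` (rate at highest / rate at lowest Ca2+),
#'   `percent_change` (100 * (fold - 1)) and `percent_decrease`
#'   (100 * (1 - fold) when fold < 1, else 0); `fold` is `NA`-flagged if
#'   the reference rate is zero or undefined.
#' @export
ca_response <- function(series, rate_col = "rate") {
  y <- series[[rate_col]]
  lo <- y[which.min(series$conc_uM)]
  hi <- y[which.max(series$conc_uM)]
  if (is.na(lo) || lo <= 0) {
    return(list(fold = NA_real_, percent_change = NA_real_,
                percent_decrease = NA_real_))
  }
  fold <- hi / lo
  list(fold = fold, percent_change = 100 * (fold - 1),
       percent_decrease = if (fold < 1) 100 * (1 - fold) else 0)
}

#' Colony-assay (blue/white) error rate
#'
#' Bulk polymerase error rate from a lacI blue/white screen:
#' `f = -ln(F) / (d * b)` with `F` the fraction of white (non-mutant)
#' colonies, `d` the number of DNA duplications and `b` the effective
#' target size in bp.  Counting uncertainty is propagated assuming Poisson
#' counts for blue and white colonies.
#'
#' @param blue,white colony counts.
#' @param d number of DNA duplications.
#' @param b effective target size in bp (default 349, the effective single-
#'   base target of the 1080-bp lacI gene).
#' @return list with `f` (errors per bp per duplication), `f_se`, and `F`
#'   (white fraction).  `F = 0` yields an infinite, flagged estimate.
#' @export
colony_error_rate <- function(blue, white, d, b = 349) {
  stopifnot(blue >= 0, white >= 0, blue + white > 0, d > 0, b > 0)
  n <- blue + white
  F <- white / n
  if (F == 0) {
    return(list(f = Inf, f_se = NA_real_, F = 0,
                flag = "no white colonies: estimate unbounded"))
  }
  f <- -log(F) / (d * b)
  # delta method: Var(ln F) = blue / (white * n) for independent Poisson counts
  f_se <- sqrt(blue / (white * n)) / (d * b)
  list(f = f, f_se = f_se, F = F)
}
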