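# Polymerase presets: a parametric model of per-template-base
# misincorporation probability as a function of the divalent cation
# condition, plus the (cation-independent) distribution of wrong incoming
# dNTPs, per-molecule rate heterogeneity, optional lag-one error coupling,
# and abortive-extension / indel probabilities.
#
# Per template base b, the pre-heterogeneity misincorporation probability is
#
#   r_b(cond) = clip( (r0_b + a_{b,Mn} * mn_mM^gamma_{b,Mn}
#                           + a_{b,Mg} * mg_mM^gamma_{b,Mg}) * ca_mult,
#                     0, r_max )
#
# where ca_mult is a piecewise log-linear fold multiplier keyed by the Ca2+
# concentration and the dominant background cation.  Each simulated molecule
# draws a unit-mean Gamma(shape k) multiplier applied to r_b; lag1_boost is
# an additive probability applied to the base immediately after an error.

#' Cation condition
#'
#' @param mn_uM,mg_uM,ca_uM concentrations in micromolar (all >= 0).
#' @return an object of class `cation_condition`.
#' @export
cation_condition <- function(mn_uM = 0, mg_uM = 0, ca_uM = 0) {
  stopifnot(mn_uM >= 0, mg_uM >= 0, ca_uM >= 0)
  structure(list(mn_uM = mn_uM, mg_uM = mg_uM, ca_uM = ca_uM),
            class = "cation_condition")
}

#' Polymerase preset constructor
#'
#' @param name preset label.
#' @param rate_params named list (`A`,`C`,`G`,`T`), each with `r0` and
#'   optional `mn`/`mg` terms (`a`, `gamma`).
#' @param transition_rows named list per template base: named probabilities
#'   over the three wrong incoming dNTPs, each summing to 1.
#' @param heterogeneity_shape Gamma shape k of the unit-mean per-molecule
#'   rate multiplier; `Inf` gives a homogeneous (Poisson) ensemble.
#' @param lag1_boost additive error probability for the base immediately
#'   after an error.
#' @param truncation_prob per-position probability of abortive termination.
#' @param indel_prob per-position insertion and deletion probability (each).
#' @param ca_modifier list of background-keyed ramps (`mn_bg`, `mg_bg`),
#'   each with `breaks_uM` (two Ca2+ breakpoints) and `mult` (fold
#'   multipliers at the breakpoints, interpolated log-linearly in between,
#'   flat outside).  `NULL` means Ca2+ has no effect.
#' @param r_max upper clip for per-base rates.
#' @return an object of class `polymerase_preset`.
#' @export
polymerase_preset <- function(name, rate_params, transition_rows,
                              heterogeneity_shape = Inf, lag1_boost = 0,
                              truncation_prob = 3e-3, indel_prob = 2e-4,
                              ca_modifier = NULL, r_max = 0.5) {
  stopifnot(setequal(names(rate_params), DNA_BASES),
            setequal(names(transition_rows), DNA_BASES),
            heterogeneity_shape > 0, lag1_boost >= 0, lag1_boost <= 1,
            truncation_prob >= 0, truncation_prob < 1,
            indel_prob >= 0, indel_prob < 1, r_max > 0, r_max <= 1)
  for (b in DNA_BASES) {
    row <- unlist(transition_rows[[b]])
    wrong <- setdiff(DNA_BASES, complement_base(b))
    if (!setequal(names(row), wrong)) {
      stop("transition row for template ", b,
           " must be keyed by the three wrong dNTPs: ",
           paste(wrong, collapse = "/"))
    }
    if (abs(sum(row) - 1) > 1e-8 || any(row < 0)) {
      stop("transition row for template ", b, " must be a distribution")
    }
  }
  structure(list(name = name, rate_params = rate_params,
                 transition_rows = lapply(transition_rows, unlist),
                 heterogeneity_shape = heterogeneity_shape,
                 lag1_boost = lag1_boost,
                 truncation_prob = truncation_prob,
                 indel_prob = indel_prob,
                 ca_modifier = ca_modifier,
                 r_max = r_max),
            class = "polymerase_preset")
}

# Ca2+ fold multiplier for a condition.  The ramp is selected by the
# dominant background cation (Mn2+ if present, else Mg2+); interpolation is
# linear in log10(ca_uM) between the two breakpoints and flat outside.
ca_multiplier <- function(preset, cond) {
  mod <- preset$ca_modifier
  if (is.null(mod) || cond$ca_uM <= 0) return(1)
  ramp <- if (cond$mn_uM > 0) mod$mn_bg else if (cond$mg_uM > 0) mod$mg_bg
  if (is.null(ramp)) return(1)
  br <- ramp$breaks_uM; mu <- ramp$mult
  lx <- log10(cond$ca_uM)
  l1 <- log10(br[1]); l2 <- log10(br[2])
  if (lx <= l1) return(mu[1])
  if (lx >= l2) return(mu[2])
  w <- (lx - l1) / (l2 - l1)
  # log-linear in the multiplier as well, so ramps cross decades smoothly
  exp((1 - w) * log(mu[1]) + w * log(mu[2]))
}

#' Analytic per-base misincorporation probability
#'
#' Evaluates the exact pre-heterogeneity, pre-coupling misincorporation
#' probability the simulator uses for one template base under a cation
#' condition.  This is the analytic ground truth against which pipeline
#' estimates are checked.
#'
#' @param preset a [polymerase_preset()].
#' @param base template base, one of `"A","C","G","T"`.
#' @param cond a [cation_condition()].
#' @return probability in `[0, r_max]`.
#' @export
rate_oracle <- function(preset, base, cond) {
  stopifnot(base %in% DNA_BASES, inherits(cond, "cation_condition"))
  rp <- preset$rate_params[[base]]
  r <- rp$r0 %||% 0
  if (!is.null(rp$mn) && cond$mn_uM > 0) {
    r <- r + rp$mn$a * (cond$mn_uM / 1000)^rp$mn$gamma
  }
  if (!is.null(rp$mg) && cond$mg_uM > 0) {
    r <- r + rp$mg$a * (cond$mg_uM / 1000)^rp$mg$gamma
  }
  clip01(r * ca_multiplier(preset, cond), 0, preset$r_max)
}

# vector of the four per-base rates for a condition
rate_vector <- function(preset, cond) {
  vapply(DNA_BASES, function(b) rate_oracle(preset, b, cond), numeric(1))
}

#' Load a bundled or user polymerase preset
#'
#' Presets are stored as YAML; the package bundles `dpo4_paper` (a
#' manganese-sensing Y-family polymerase with template-T-dominated errors),
#' `klenow_paper` (a proofreading-deficient Klenow-fragment-like enzyme with
#' lag-one error coupling and a dATP-dominated transition structure), and
#' `phusion_control` (a high-fidelity control with zero polymerase errors,
#' used to measure the template-synthesis noise floor).
#'
#' @param name preset name, or a path to a YAML file containing one preset.
#' @return a [polymerase_preset()].
#' @export
load_preset <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", "presets.yaml", package = "polyrec")
  defs <- yaml::read_yaml(path)
  if (!is.null(defs$name)) {       # single-preset file
    def <- defs
  } else {
    def <- defs[[name]]
    if (is.null(def)) {
      stop("unknown preset '", name, "'; bundled presets: ",
           paste(names(defs), collapse = ", "))
    }
  }
  ca_mod <- def$ca_modifier
  if (!is.null(ca_mod)) {
    ca_mod <- lapply(ca_mod, function(ramp)
      list(breaks_uM = as.numeric(unlist(ramp$breaks_uM)),
           mult = as.numeric(unlist(ramp$mult))))
  }
  polymerase_preset(
    name = def$name %||% name,
    rate_params = def$rate_params,
    transition_rows = def$transition_rows,
    heterogeneity_shape = if (identical(def$heterogeneity_shape, "Inf"))
      Inf else def$heterogeneity_shape,
    lag1_boost = def$lag1_boost %||% 0,
    truncation_prob = def$truncation_prob %||% 3e-3,
    indel_prob = def$indel_prob %||% 2e-4,
    ca_modifier = ca_mod,
    r_max = def$r_max %||% 0.5
  )
}

#' @export
print.polymerase_preset <- function(x, ...) {
  cat("Polymerase preset", x$name, "\n")
  cat("  heterogeneity shape:", x$heterogeneity_shape,
      " lag-1 boost:", x$lag1_boost, "\n")
  cat("  truncation:", x$truncation_prob, "/position, indel:",
      x$indel_prob, "/position\n")
  invisible(x)
}
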