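# Shared fixtures and independent oracles for the test suite.

# Independent affine-gap global alignment oracle (Gotoh three-state DP).
# End gaps are scored; a gap of length L costs open + extend * (L - 1).
# Kept deliberately simple and slow - it is the ground truth the fast
# aligner is checked against.
gotoh_score <- function(a, b, match = 1, mismatch = 0, open = 10, extend = 2) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)   # gap in b (vertical)
  Iy <- matrix(NEG, n + 1, m + 1)   # gap in a (horizontal)
  M[1, 1] <- 0
  if (n >= 1) for (i in 2:(n + 1)) Ix[i, 1] <- -open - extend * (i - 2)
  if (m >= 1) for (j in 2:(m + 1)) Iy[1, j] <- -open - extend * (j - 2)
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
      Ix[i, j] <- max(M[i - 1, j] - open, Ix[i - 1, j] - extend,
                      Iy[i - 1, j] - open)
      Iy[i, j] <- max(M[i, j - 1] - open, Iy[i, j - 1] - extend,
                      Ix[i, j - 1] - open)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# Brute-force mutual information I(state; outcome) of the 2x2 joint
# distribution defined by a binary channel - the independent oracle for
# info_gain().
mi_oracle <- function(p_I_H, p_I_L, prior_H = 0.5, prior_L = 0.5) {
  joint <- rbind(H = prior_H * c(I = p_I_H, C = 1 - p_I_H),
                 L = prior_L * c(I = p_I_L, C = 1 - p_I_L))
  ps <- rowSums(joint); po <- colSums(joint)
  mi <- 0
  for (s in 1:2) for (o in 1:2) {
    if (joint[s, o] > 0) {
      mi <- mi + joint[s, o] * log2(joint[s, o] / (ps[s] * po[o]))
    }
  }
  unname(mi)
}

random_dna <- function(n, len) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), n, len)
  apply(m, 1, paste, collapse = "")
}

# A flat preset with identical per-base rates, no cation dependence and no
# nuisance processes - handy analytic ground truth for estimator tests.
flat_preset <- function(rate = 0, heterogeneity_shape = Inf, lag1_boost = 0,
                        truncation_prob = 0, indel_prob = 0,
                        rows = NULL) {
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (is.null(rows)) {
    rows <- lapply(setNames(bases, bases), function(b) {
      w <- setdiff(bases, comp[[b]])
      setNames(rep(1 / 3, 3), w)
    })
  }
  polymerase_preset(
    name = "flat_test",
    rate_params = lapply(setNames(bases, bases), function(b) list(r0 = rate)),
    transition_rows = rows,
    heterogeneity_shape = heterogeneity_shape, lag1_boost = lag1_boost,
    truncation_prob = truncation_prob, indel_prob = indel_prob)
}

# small simulate -> filter -> quantify convenience used by several files
run_small_pipeline <- function(plate, preset, template, seed,
                               noise_sub_prob = 1e-3, dimer_frac = 0.05,
                               ...) {
  sim <- simulate_plate(plate, preset, template, seed = seed,
                        noise_sub_prob = noise_sub_prob,
                        dimer_frac = dimer_frac)
  cfg <- filter_config(plate$barcode_set)
  demux <- filter_and_demux(sim$fwd, sim$rev, cfg, wells = plate$wells)
  quant <- quantify_plate(demux, plate, template, ...)
  list(sim = sim, demux = demux, quant = quant)
}
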