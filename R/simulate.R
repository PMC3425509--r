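# Synthetic plate generator.  Emulates the biochemical steps of the
# barcoded primer-extension assay in silico: per-molecule polymerase walks
# over the template extension region with cation-dependent per-base
# misincorporation, fixed wrong-dNTP transition distributions, Gamma
# molecule-to-molecule rate heterogeneity, optional lag-one error coupling,
# abortive extensions, rare indels, a template-synthesis substitution noise
# floor, and a known primer-dimer contaminant.

DIMER_INSERT_DEFAULT <- "ACGCATGCTT"  # insert of the spurious primer-dimer product

# Vectorised polymerase walk for n molecules at one condition.  Assumes the
# RNG is already seeded by the caller.  Noise-floor substitutions mutate the
# template copy before the polymerase copies it (emulating synthesis
# impurities), so the polymerase incorporates the Watson-Crick complement of
# the mutated base unless it makes its own error.
simulate_molecules <- function(template, preset, cond, n,
                               noise_sub_prob = 1e-3) {
  L <- template$ext_len
  tb_codes <- match(template$template_ext_order, DNA_BASES)
  rb <- rate_vector(preset, cond)
  k <- preset$heterogeneity_shape
  mult <- if (is.finite(k)) rgamma(n, shape = k, rate = k) else rep(1, n)

  tbmat <- matrix(rep(tb_codes, each = n), nrow = n, ncol = L)
  noise_idx <- integer(0)
  if (noise_sub_prob > 0) {
    noise_idx <- which(runif(n * L) < noise_sub_prob)
    if (length(noise_idx)) {
      shift <- sample.int(3L, length(noise_idx), replace = TRUE)
      tbmat[noise_idx] <- ((tbmat[noise_idx] - 1L + shift) %% 4L) + 1L
    }
  }

  rmat <- matrix(rb[tbmat], nrow = n, ncol = L)
  err <- matrix(FALSE, n, L)
  eps <- preset$lag1_boost
  prev <- rep(FALSE, n)
  for (p in seq_len(L)) {
    pr <- clip01(mult * rmat[, p] + eps * prev)
    err[, p] <- runif(n) < pr
    prev <- err[, p]
  }

  prod <- 5L - tbmat                     # complement code (A1<->T4, C2<->G3)
  err_idx <- which(err)
  if (length(err_idx)) {
    tbase <- tbmat[err_idx]
    for (bi in 1:4) {
      sel <- which(tbase == bi)
      if (!length(sel)) next
      row <- preset$transition_rows[[DNA_BASES[bi]]]
      wrong_codes <- match(names(row), DNA_BASES)
      prod[err_idx[sel]] <- wrong_codes[sample.int(
        length(row), length(sel), replace = TRUE, prob = row)]
    }
  }

  tr <- preset$truncation_prob
  len <- if (tr > 0) pmin(rgeom(n, tr), L) else rep.int(L, n)

  chars <- DNA_BASES[prod]
  dim(chars) <- dim(prod)
  insert <- substr(paste_rows(chars), 1L, len)

  # sparse event records (positions in extension order)
  ev <- data.frame(read = integer(0), pos = integer(0),
                   type = character(0), obs = character(0))
  if (length(err_idx)) {
    ev <- rbind(ev, data.frame(
      read = ((err_idx - 1L) %% n) + 1L, pos = ((err_idx - 1L) %/% n) + 1L,
      type = "X", obs = DNA_BASES[prod[err_idx]]))
  }
  if (length(noise_idx)) {
    ev <- rbind(ev, data.frame(
      read = ((noise_idx - 1L) %% n) + 1L,
      pos = ((noise_idx - 1L) %/% n) + 1L,
      type = "N", obs = DNA_BASES[5L - tbmat[noise_idx]]))
  }
  ev <- ev[ev$pos <= len[ev$read], , drop = FALSE]

  # rare indels, applied read-by-read to the realised insert
  ip <- preset$indel_prob
  if (ip > 0) {
    n_ins <- rbinom(n, len, ip)
    n_del <- rbinom(n, len, ip)
    touched <- which(n_ins + n_del > 0 & len > 0)
    for (i in touched) {
      s <- split_chars(insert[i])[[1L]]
      if (n_del[i] > 0) {
        dp <- sort(sample.int(length(s), min(n_del[i], length(s))))
        ev <- rbind(ev, data.frame(read = i, pos = dp, type = "D", obs = "-"))
        s <- s[-dp]
      }
      if (n_ins[i] > 0 && length(s) > 0) {
        for (j in seq_len(n_ins[i])) {
          at <- sample.int(length(s), 1L)
          nb <- sample(DNA_BASES, 1L)
          ev <- rbind(ev, data.frame(read = i, pos = at, type = "I", obs = nb))
          s <- append(s, nb, after = at)
        }
      }
      insert[i] <- paste(s, collapse = "")
    }
  }

  events <- character(n)
  if (nrow(ev)) {
    ev <- ev[order(ev$read, ev$pos), , drop = FALSE]
    lab <- sprintf("%d%s%s", ev$pos, ev$type,
                   ifelse(ev$obs == "-", "", ev$obs))
    joined <- vapply(split(lab, factor(ev$read, levels = seq_len(n))),
                     paste, character(1), collapse = ";")
    events <- unname(joined)
  }
  n_poly <- tabulate(ev$read[ev$type == "X"], nbins = n)
  n_noise <- tabulate(ev$read[ev$type == "N"], nbins = n)

  list(insert = insert, length = nchar(insert),
       n_poly = n_poly, n_noise = n_noise, events = events)
}

#' Simulate primer extension for one or more molecules
#'
#' Walks the template extension region 5'->3' on the product strand: each
#' molecule draws a unit-mean Gamma rate multiplier; at every position the
#' error probability is `clip(mult * r_b + lag1_boost * [error at previous
#' position], 0, 1)`; errors draw a wrong dNTP from the preset's transition
#' row for the template base, otherwise the Watson-Crick complement of the
#' (possibly noise-mutated) template base is incorporated.  Abortive
#' termination and indels are applied with the preset's probabilities.
#'
#' @param template a [template_spec()].
#' @param preset a [polymerase_preset()].
#' @param cond a [cation_condition()].
#' @param n number of molecules.
#' @param seed integer seed.
#' @param noise_sub_prob per-position template-synthesis substitution
#'   probability (the experimental noise floor; 0 disables it).
#' @return list with `insert` (product sequences 5'->3'), `length`,
#'   `n_poly`/`n_noise` per-molecule event counts, and `events` (compact
#'   per-molecule strings like `"12XG;40NT;55D"`: position in extension
#'   order, type X = polymerase misincorporation, N = noise substitution,
#'   I/D = insertion/deletion, then the observed base).
#' @export
simulate_extension <- function(template, preset, cond, n = 1L, seed = 1L,
                               noise_sub_prob = 0) {
  with_seed(seed,
            simulate_molecules(template, preset, cond, n, noise_sub_prob))
}

#' Simulate a full barcoded plate as paired FASTQ
#'
#' Generates `reads_per_well` read pairs per well plus a configurable
#' fraction of primer-dimer contaminant pairs.  Forward reads have layout
#' `barcode + left primer-binding sequence + product + first 12 bases of the
#' right adapter`; reverse reads are the reverse complement of `barcode +
#' left primer-binding sequence + product`.  Each well draws from its own
#' seeded stream (see [well_seed()]), so output is bit-reproducible and
#' individual wells can be regenerated in isolation.
#'
#' @param plate a [plate_design()].
#' @param preset a [polymerase_preset()] (default: load `plate$preset_name`).
#' @param template a [template_spec()].
#' @param seed integer plate seed.
#' @param out_dir if non-`NULL`, write `reads_R1.fastq`, `reads_R2.fastq`,
#'   `truth.tsv` and `plate.tsv` there.
#' @param noise_sub_prob template-synthesis substitution probability per
#'   position (default 1e-3).
#' @param dimer_frac fraction of additional primer-dimer read pairs per well.
#' @param dimer_insert insert sequence of the primer-dimer contaminant.
#' @return list with `fwd`, `rev` (named character vectors of reads; names
#'   are read ids), `truth` (data.frame: `read_id`, `well_id`,
#'   `is_primer_dimer`, `insert_len`, `n_poly_errors`, `n_noise_subs`,
#'   `events`), and `plate`.
#' @export
simulate_plate <- function(plate, preset = NULL,
                           template = bundled_template("original"),
                           seed = 1L, out_dir = NULL, noise_sub_prob = 1e-3,
                           dimer_frac = 0.05,
                           dimer_insert = DIMER_INSERT_DEFAULT) {
  if (is.null(preset)) preset <- load_preset(plate$preset_name)
  wells <- plate$wells
  n <- plate$reads_per_well
  fwd <- rev_ <- id <- character(0)
  truth <- vector("list", nrow(wells))
  reads_f <- reads_r <- ids <- vector("list", nrow(wells))
  for (i in seq_len(nrow(wells))) {
    w <- wells[i, ]
    cond <- cation_condition(w$mn_uM, w$mg_uM, w$ca_uM)
    sim <- with_seed(well_seed(seed, i), {
      mol <- simulate_molecules(template, preset, cond, n, noise_sub_prob)
      n_dim <- round(dimer_frac * n)
      list(mol = mol, n_dim = n_dim)
    })
    mol <- sim$mol
    rid <- sprintf("%s_%05d", w$well_id, seq_len(n))
    f <- paste0(w$barcode, LEFT_PRIMER_BIND, mol$insert, RIGHT_ADAPTER_PREFIX)
    r <- revcomp(paste0(w$barcode, LEFT_PRIMER_BIND, mol$insert))
    tru <- data.frame(read_id = rid, well_id = w$well_id,
                      is_primer_dimer = FALSE, insert_len = mol$length,
                      n_poly_errors = mol$n_poly, n_noise_subs = mol$n_noise,
                      events = mol$events, stringsAsFactors = FALSE)
    if (sim$n_dim > 0) {
      did <- sprintf("%s_D%04d", w$well_id, seq_len(sim$n_dim))
      f <- c(f, rep(paste0(w$barcode, LEFT_PRIMER_BIND, dimer_insert,
                           RIGHT_ADAPTER_PREFIX), sim$n_dim))
      r <- c(r, rep(revcomp(paste0(w$barcode, LEFT_PRIMER_BIND, dimer_insert)),
                    sim$n_dim))
      rid <- c(rid, did)
      tru <- rbind(tru, data.frame(
        read_id = did, well_id = w$well_id, is_primer_dimer = TRUE,
        insert_len = nchar(dimer_insert), n_poly_errors = 0L,
        n_noise_subs = 0L, events = "", stringsAsFactors = FALSE))
    }
    reads_f[[i]] <- f; reads_r[[i]] <- r; ids[[i]] <- rid; truth[[i]] <- tru
  }
  fwd <- unlist(reads_f); rev_ <- unlist(reads_r); id <- unlist(ids)
  names(fwd) <- names(rev_) <- id
  truth <- do.call(rbind, truth)
  out <- list(fwd = fwd, rev = rev_, truth = truth, plate = plate)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fastq(fwd, file.path(out_dir, "reads_R1.fastq"))
    write_fastq(rev_, file.path(out_dir, "reads_R2.fastq"))
    write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_plate_tsv(plate, file.path(out_dir, "plate.tsv"))
    out$files <- file.path(out_dir, c("reads_R1.fastq", "reads_R2.fastq",
                                      "truth.tsv", "plate.tsv"))
  }
  out
}

#' Write reads as 4-line FASTQ with placeholder qualities
#'
#' The analysis never uses quality scores, so a constant `I` placeholder is
#' written for every base.
#'
#' @param reads named character vector (names become read ids).
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  quals <- Biostrings::BStringSet(strrep("I", nchar(reads)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#'
#' @param path FASTQ file.
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Toy per-position secondary-structure profile
#'
#' A deterministic stand-in for an ensemble pairing-probability profile:
#' for every template position (in extension order) it reports the best
#' antiparallel self-complementarity over all window-sized pairings with the
#' rest of the extension region, scaled to `[0, 1]`.  This is a synthetic
#' profile for building structure covariates when no thermodynamic
#' prediction is available; it makes no claim of agreement with
#' partition-function calculations.
#'
#' @param template a [template_spec()].
#' @param window odd window size (>= 3) over which complementarity is
#'   averaged.
#' @param min_loop minimum separation between paired windows.
#' @return data.frame with `position` (extension order) and `s` in `[0,1]`.
#' @export
toy_structure_profile <- function(template, window = 5L, min_loop = 3L) {
  stopifnot(window >= 3)
  s <- template$template_ext_order
  L <- length(s)
  comp <- complement_base(s)
  C <- outer(s, comp, "==") * 1           # C[i,j]: s[i] pairs with s[j]
  h <- (window - 1L) %/% 2L
  M <- matrix(0, L, L)
  cnt <- matrix(0, L, L)
  for (d in -h:h) {
    ii <- seq_len(L) + d
    ok_i <- ii >= 1 & ii <= L
    jj <- seq_len(L) - d
    ok_j <- jj >= 1 & jj <= L
    M[ok_i, ok_j] <- M[ok_i, ok_j] + C[ii[ok_i], jj[ok_j]]
    cnt[ok_i, ok_j] <- cnt[ok_i, ok_j] + 1
  }
  score <- M / cnt
  near <- abs(outer(seq_len(L), seq_len(L), "-")) <= min_loop
  score[near] <- 0
  data.frame(position = seq_len(L), s = apply(score, 1, max))
}
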