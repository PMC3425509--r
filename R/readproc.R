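# Read filtering and demultiplexing.  Forward reads must contain the left
# primer-binding sequence, the first 12 bases of the right adapter, and a
# barcode exactly matching the set; reverse reads must contain the left
# primer-binding sequence and the barcode; mates whose inserts do not match
# exactly are discarded; the known primer-dimer contaminant is removed and
# counted.  All landmark matching is exact (slack 0 by default): with a
# barcode set of pairwise Levenshtein distance >= 2, exact matching can
# never misassign a read with a single barcode error.

REJECT_REASONS <- c("no_left_primer", "no_right_adapter", "bad_barcode",
                    "pair_mismatch", "primer_dimer", "accepted")

#' Filter configuration
#'
#' @param barcode_set a [generate_barcodes()] result or a plain character
#'   vector of barcodes.
#' @param left_primer_bind_seq sequence of the primer's template-annealing
#'   3' tail, expected immediately after the barcode.
#' @param right_adapter_prefix first 12 bases of the ligated right adapter.
#' @param primer_dimer_seq insert sequence of the known primer-dimer
#'   contaminant (`NULL` disables dimer filtering).
#' @param barcode_offset 1-based position of the barcode in the read.
#' @return object of class `filter_config`.
#' @export
filter_config <- function(barcode_set,
                          left_primer_bind_seq = LEFT_PRIMER_BIND,
                          right_adapter_prefix = RIGHT_ADAPTER_PREFIX,
                          primer_dimer_seq = DIMER_INSERT_DEFAULT,
                          barcode_offset = 1L) {
  barcodes <- if (inherits(barcode_set, "barcode_set"))
    barcode_set$barcodes else as.character(barcode_set)
  stopifnot(length(barcodes) >= 1,
            length(unique(nchar(barcodes))) == 1,
            nchar(right_adapter_prefix) == 12L)
  structure(list(barcodes = barcodes,
                 barcode_len = nchar(barcodes[1]),
                 left_primer_bind_seq = left_primer_bind_seq,
                 right_adapter_prefix = right_adapter_prefix,
                 primer_dimer_seq = primer_dimer_seq,
                 barcode_offset = as.integer(barcode_offset)),
            class = "filter_config")
}

# Vectorised landmark extraction shared by both directions.  Reverse reads
# are reverse-complemented first so that both directions present the layout
# barcode + left primer + insert (+ adapter, forward only).
extract_insert_vec <- function(reads, cfg, direction) {
  n <- length(reads)
  if (direction == "reverse") {
    reads <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(reads)))
  }
  bl <- cfg$barcode_len
  off <- cfg$barcode_offset
  lp <- cfg$left_primer_bind_seq
  lp_len <- nchar(lp)
  reason <- rep(NA_character_, n)
  barcode <- insert <- rep(NA_character_, n)

  min_len <- off - 1L + bl + lp_len
  too_short <- nchar(reads) < min_len
  lp_at <- substr(reads, off + bl, off + bl + lp_len - 1L)
  no_lp <- too_short | lp_at != lp
  reason[no_lp] <- "no_left_primer"

  ok <- !no_lp
  barcode[ok] <- substr(reads[ok], off, off + bl - 1L)
  ins_start <- off + bl + lp_len
  if (direction == "forward") {
    ad_pos <- rep(-1L, n)
    ad_pos[ok] <- regexpr(cfg$right_adapter_prefix, substring(reads[ok], ins_start),
                          fixed = TRUE)
    no_ad <- ok & ad_pos < 1L
    reason[no_ad] <- "no_right_adapter"
    ok <- ok & !no_ad
    insert[ok] <- substr(reads[ok], ins_start, ins_start + ad_pos[ok] - 2L)
  } else {
    insert[ok] <- substring(reads[ok], ins_start)
  }
  bad_bc <- ok & !(barcode %in% cfg$barcodes)
  reason[bad_bc] <- "bad_barcode"
  ok <- ok & !bad_bc
  list(ok = ok, reason = reason, barcode = barcode, insert = insert)
}

#' Extract barcode and insert from a single read
#'
#' @param read a read sequence.
#' @param cfg a [filter_config()].
#' @param direction `"forward"` or `"reverse"`.
#' @return list with either `barcode` and `insert`, or `reason` (one of
#'   `"no_left_primer"`, `"no_right_adapter"`, `"bad_barcode"`).  Never
#'   throws on malformed reads.
#' @export
extract_insert <- function(read, cfg, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  r <- extract_insert_vec(read, cfg, direction)
  if (r$ok[1]) list(barcode = r$barcode[1], insert = r$insert[1])
  else list(reason = r$reason[1])
}

#' Exact paired-end insert agreement
#'
#' Accepts a pair if and only if the forward insert equals the insert
#' recovered from the reverse mate (already rendered on the forward strand),
#' character for character.
#'
#' @param fwd_insert,rev_insert extracted inserts.
#' @return `TRUE` to accept, `FALSE` to reject.
#' @export
pair_filter <- function(fwd_insert, rev_insert) {
  !is.na(fwd_insert) & !is.na(rev_insert) & fwd_insert == rev_insert
}

#' Filter and demultiplex a read-pair set
#'
#' Applies the forward and reverse landmark filters, the exact pair-match
#' rule and the primer-dimer filter, then routes inserts to wells by exact
#' barcode match.  Every input pair is assigned exactly one outcome, so the
#' per-reason counts partition the input.
#'
#' @param fwd,rev paired reads: character vectors or FASTQ file paths.
#' @param cfg a [filter_config()].
#' @param wells optional data.frame with `well_id` and `barcode` mapping
#'   barcodes to well ids (defaults to one well per barcode).
#' @return list with `wells` (named list of per-well insert vectors, names
#'   carry read ids), `assign` (data.frame: `read_id`, `outcome`, `well_id`)
#'   and `stats` (data.frame of `reason`/`count`, including `accepted`).
#' @export
filter_and_demux <- function(fwd, rev, cfg, wells = NULL) {
  if (length(fwd) == 1L && file.exists(fwd)) fwd <- read_fastq(fwd)
  if (length(rev) == 1L && file.exists(rev)) rev <- read_fastq(rev)
  if (length(fwd) != length(rev)) {
    stop("forward and reverse files differ in read count (",
         length(fwd), " vs ", length(rev), ")")
  }
  n <- length(fwd)
  ids <- names(fwd) %||% as.character(seq_len(n))
  if (is.null(wells)) {
    wells <- data.frame(well_id = cfg$barcodes, barcode = cfg$barcodes,
                        stringsAsFactors = FALSE)
  }
  f <- extract_insert_vec(unname(fwd), cfg, "forward")
  r <- extract_insert_vec(unname(rev), cfg, "reverse")

  outcome <- rep("accepted", n)
  # first failing check wins, forward filters before reverse
  outcome[r$reason == "bad_barcode" & !is.na(r$reason)] <- "bad_barcode"
  outcome[r$reason == "no_left_primer" & !is.na(r$reason)] <- "no_left_primer"
  outcome[!is.na(f$reason)] <- f$reason[!is.na(f$reason)]
  und <- outcome == "accepted"
  mism <- und & (!pair_filter(f$insert, r$insert) | f$barcode != r$barcode)
  outcome[mism] <- "pair_mismatch"
  und <- outcome == "accepted"
  if (!is.null(cfg$primer_dimer_seq)) {
    outcome[und & f$insert == cfg$primer_dimer_seq] <- "primer_dimer"
    und <- outcome == "accepted"
  }

  wmap <- setNames(wells$well_id, wells$barcode)
  well_id <- rep(NA_character_, n)
  well_id[und] <- wmap[f$barcode[und]]
  # accepted barcode not on this plate: treat as bad_barcode
  orphan <- und & is.na(well_id)
  outcome[orphan] <- "bad_barcode"
  und <- outcome == "accepted"

  per_well <- lapply(setNames(wells$well_id, wells$well_id), function(w) {
    sel <- which(und & well_id == w)
    setNames(f$insert[sel], ids[sel])
  })
  stats <- data.frame(reason = REJECT_REASONS,
                      count = vapply(REJECT_REASONS,
                                     function(rr) sum(outcome == rr),
                                     integer(1)))
  rownames(stats) <- NULL
  list(wells = per_well,
       assign = data.frame(read_id = ids, outcome = outcome,
                           well_id = well_id, stringsAsFactors = FALSE),
       stats = stats)
}
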