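# Plate designs: wells with barcode, cation condition and replicate group.
# Every condition appears in >= 2 wells with distinct barcodes so that
# replicate means and their standard errors can be formed downstream.

#' Default titration grids
#'
#' Mn2+ titrations use \{10, 25, 75, 200, 400, 800\} uM and Mg2+ titrations
#' \{1000, 2000, 4000, 7000\} uM; these grids bracket the concentrations at
#' which the bundled presets were characterised and give a stable ordinary
#' least-squares slope.
#'
#' @param cation `"mn"` or `"mg"`.
#' @return numeric vector of concentrations in uM.
#' @export
default_grid <- function(cation = c("mn", "mg")) {
  cation <- match.arg(cation)
  switch(cation, mn = c(10, 25, 75, 200, 400, 800),
         mg = c(1000, 2000, 4000, 7000))
}

#' Build a plate design
#'
#' @param conditions data.frame with columns `mn_uM`, `mg_uM`, `ca_uM`
#'   (one row per condition).
#' @param n_replicates wells per condition (default 2, "duplicate wells").
#' @param reads_per_well reads simulated per well.
#' @param preset_name label of the polymerase preset to be used.
#' @param barcode_set a [generate_barcodes()] result, or `NULL` to generate
#'   one deterministically from `barcode_seed`.
#' @param barcode_seed seed for barcode generation when `barcode_set` is
#'   `NULL`.
#' @return object of class `plate_design`: list with `wells` (data.frame:
#'   `well_id`, `barcode`, `mn_uM`, `mg_uM`, `ca_uM`, `replicate_group`),
#'   `reads_per_well`, `preset_name`.
#' @export
plate_design <- function(conditions, n_replicates = 2L, reads_per_well = 2000L,
                         preset_name = "dpo4_paper", barcode_set = NULL,
                         barcode_seed = 7L) {
  stopifnot(is.data.frame(conditions),
            all(c("mn_uM", "mg_uM", "ca_uM") %in% names(conditions)),
            n_replicates >= 1, reads_per_well >= 1)
  n_wells <- nrow(conditions) * n_replicates
  if (is.null(barcode_set)) {
    barcode_set <- generate_barcodes(n_wells, 5L, 2L, seed = barcode_seed)
  }
  if (length(barcode_set$barcodes) < n_wells) {
    stop("barcode set has fewer barcodes than wells")
  }
  idx <- rep(seq_len(nrow(conditions)), each = n_replicates)
  wells <- data.frame(
    well_id = sprintf("W%02d", seq_len(n_wells)),
    barcode = barcode_set$barcodes[seq_len(n_wells)],
    mn_uM = conditions$mn_uM[idx],
    mg_uM = conditions$mg_uM[idx],
    ca_uM = conditions$ca_uM[idx],
    replicate_group = sprintf("C%02d", idx),
    stringsAsFactors = FALSE
  )
  structure(list(wells = wells, reads_per_well = as.integer(reads_per_well),
                 preset_name = preset_name, barcode_set = barcode_set),
            class = "plate_design")
}

#' Titration plate along one cation
#'
#' Convenience wrapper building a duplicate-well plate varying one cation
#' over a grid at a fixed background of the others.
#'
#' @param cation `"mn"`, `"mg"` or `"ca"`.
#' @param grid_uM concentrations in uM (default [default_grid()] for Mn/Mg).
#' @param background named list with fixed `mn_uM`/`mg_uM`/`ca_uM` values.
#' @inheritParams plate_design
#' @export
titration_plate <- function(cation = c("mn", "mg", "ca"), grid_uM = NULL,
                            background = list(), n_replicates = 2L,
                            reads_per_well = 2000L,
                            preset_name = "dpo4_paper", barcode_seed = 7L) {
  cation <- match.arg(cation)
  if (is.null(grid_uM)) {
    if (cation == "ca") stop("a Ca2+ titration needs an explicit grid_uM")
    grid_uM <- default_grid(cation)
  }
  base <- list(mn_uM = 0, mg_uM = 0, ca_uM = 0)
  base[names(background)] <- background
  conditions <- data.frame(mn_uM = base$mn_uM, mg_uM = base$mg_uM,
                           ca_uM = base$ca_uM)[rep(1, length(grid_uM)), ]
  conditions[[paste0(cation, "_uM")]] <- sort(grid_uM)
  rownames(conditions) <- NULL
  plate_design(conditions, n_replicates = n_replicates,
               reads_per_well = reads_per_well, preset_name = preset_name,
               barcode_seed = barcode_seed)
}

#' Read/write plate designs as TSV
#'
#' @param plate a [plate_design()].
#' @param path file path.
#' @export
write_plate_tsv <- function(plate, path) {
  write.table(plate$wells, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plate_tsv
#' @param reads_per_well,preset_name metadata restored alongside the wells.
#' @export
read_plate_tsv <- function(path, reads_per_well = 2000L,
                           preset_name = "dpo4_paper") {
  wells <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("well_id", "barcode", "mn_uM", "mg_uM", "ca_uM", "replicate_group")
  if (!all(need %in% names(wells))) {
    stop("plate TSV must have columns: ", paste(need, collapse = ", "))
  }
  structure(list(wells = wells[need], reads_per_well = as.integer(reads_per_well),
                 preset_name = preset_name,
                 barcode_set = structure(list(barcodes = wells$barcode,
                                              min_pairwise_levenshtein = NA_integer_),
                                         class = "barcode_set")),
            class = "plate_design")
}

#' @export
print.plate_design <- function(x, ...) {
  cat("Plate design:", nrow(x$wells), "wells,", x$reads_per_well,
      "reads/well, preset", x$preset_name, "\n")
  invisible(x)
}
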