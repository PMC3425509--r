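# End-to-end orchestration: simulate -> filter -> quantify -> transfer /
# stats / info, with every intermediate written as plain TSV and a manifest
# recording the seed, package version and input digests so that a rerun
# with the same configuration is bit-identical.

#' Run the full pipeline on a simulated plate
#'
#' @param config list with elements `template` (name or [template_spec()]),
#'   `preset` (name or [polymerase_preset()]), `plate` (a [plate_design()]
#'   or path to a plate TSV), `seed` (integer), optional `varied`
#'   (`"mn"`, `"mg"` or `"ca"`; default inferred from the plate), optional
#'   `noise_sub_prob`, `dimer_frac`, `alignment` ([alignment_params()]),
#'   `reads_per_well` (for TSV plates), and optional `out_dir`.
#' @param stages character vector of stages to run after simulate/filter/
#'   quantify; any of `"transfer"`, `"stats"`, `"info"`.
#' @return report list with `filter_stats`, `well_rates`, `series`,
#'   `transfer` (gain fit), `stats` (lag-one + dispersion, when requested),
#'   `info` (when the plate contains exactly two conditions), and
#'   `manifest`.
#' @export
run_all <- function(config, stages = c("transfer", "stats")) {
  cfg <- config
  stopifnot(is.list(cfg), !is.null(cfg$seed))
  template <- if (inherits(cfg$template, "template_spec")) cfg$template
  else bundled_template(cfg$template %||% "original")
  preset <- if (inherits(cfg$preset, "polymerase_preset")) cfg$preset
  else load_preset(cfg$preset %||% "dpo4_paper")
  plate <- cfg$plate
  if (is.character(plate)) {
    if (!file.exists(plate)) stop("plate file not found: ", plate)
    plate <- read_plate_tsv(plate, reads_per_well = cfg$reads_per_well %||% 2000L,
                            preset_name = preset$name)
  }
  stopifnot(inherits(plate, "plate_design"))
  params <- cfg$alignment %||% alignment_params()
  out_dir <- cfg$out_dir

  sim <- simulate_plate(plate, preset, template, seed = cfg$seed,
                        out_dir = out_dir,
                        noise_sub_prob = cfg$noise_sub_prob %||% 1e-3,
                        dimer_frac = cfg$dimer_frac %||% 0.05)
  fcfg <- filter_config(plate$barcode_set)
  demux <- filter_and_demux(sim$fwd, sim$rev, fcfg, wells = plate$wells)
  quant <- quantify_plate(demux, plate, template, params)

  report <- list(filter_stats = demux$stats, well_rates = quant$well_rates,
                 tallies = quant$tallies)

  varied <- cfg$varied %||% {
    spans <- vapply(c("mn", "mg", "ca"), function(ct)
      length(unique(plate$wells[[paste0(ct, "_uM")]])), integer(1))
    c("mn", "mg", "ca")[which.max(spans)]
  }
  if ("transfer" %in% stages) {
    series <- titration_series(quant$well_rates, varied)
    report$series <- series
    report$transfer <- c(list(varied = varied), fit_gain(series))
    if (varied == "ca") report$ca_response <- ca_response(series)
  }
  if ("stats" %in% stages) {
    top <- plate$wells$well_id[which.max(plate$wells[[paste0(varied, "_uM")]])]
    q <- quantify_well(demux$wells[[top]], template, params,
                       keep_error_matrix = TRUE)
    if (nrow(q$error_matrix) >= 30) {
      report$stats <- list(
        well_id = top,
        lag_one = lag_one_excess(q$error_matrix, seed = cfg$seed),
        dispersion = dispersion_test(q$error_matrix))
    }
  }
  if ("info" %in% stages) {
    groups <- split(plate$wells$well_id, plate$wells$replicate_group)
    if (length(groups) == 2) {
      conc <- vapply(plate$wells[[paste0(varied, "_uM")]],
                     identity, numeric(1))
      by_grp <- split(conc, plate$wells$replicate_group)
      ord <- order(vapply(by_grp, `[`, numeric(1), 1))
      lo_wells <- groups[[ord[1]]]; hi_wells <- groups[[ord[2]]]
      pool <- function(ws) misincorporation_rates(
        combine_tallies(quant$tallies[ws]))$per_position
      report$info <- info_profile(pool(hi_wells), pool(lo_wells))
    }
  }

  manifest <- list(
    package_version = as.character(packageVersion("polyrec")),
    seed = cfg$seed, preset = preset$name, template = template$name,
    wells = nrow(plate$wells), reads_per_well = plate$reads_per_well)
  if (!is.null(out_dir)) {
    write.table(demux$stats, file.path(out_dir, "filter_stats.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(quant$well_rates, file.path(out_dir, "well_rates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    ins_dir <- file.path(out_dir, "inserts")
    dir.create(ins_dir, showWarnings = FALSE)
    for (w in names(demux$wells)) {
      if (length(demux$wells[[w]])) {
        Biostrings::writeXStringSet(
          Biostrings::DNAStringSet(demux$wells[[w]]),
          file.path(ins_dir, paste0(w, ".fasta")))
      }
    }
    pooled_tm <- transition_matrix(combine_tallies(quant$tallies))
    write.table(data.frame(template_base = rownames(pooled_tm),
                           round(pooled_tm, 6)),
                file.path(out_dir, "transitions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(report$series)) {
      write.table(as.data.frame(report$series),
                  file.path(out_dir, "titration.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(report$info)) {
      write.table(report$info$profile, file.path(out_dir, "info_profile.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    digests <- tools::md5sum(
      file.path(out_dir, c("reads_R1.fastq", "reads_R2.fastq")))
    manifest$input_digests <- as.list(setNames(unname(digests),
                                               basename(names(digests))))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  report$manifest <- manifest
  report
}
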