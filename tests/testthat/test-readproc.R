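tpl <- bundled_template("original")
LP <- "GATGGTCATAGCTGTTGTA"
AD <- "AGATCGGAAGAG"

bc <- generate_barcodes(4, 5, 2, seed = 9)
cfg <- filter_config(bc)

test_that("extract_insert recovers barcode and insert from well-formed reads", {
  read <- paste0(bc$barcodes[1], LP, tpl$product_ref, AD)
  r <- extract_insert(read, cfg, "forward")
  expect_identical(r$barcode, bc$barcodes[1])
  expect_identical(r$insert, tpl$product_ref)
  expect_equal(nchar(r$insert), 76)
  rr <- extract_insert(revcomp(paste0(bc$barcodes[1], LP, tpl$product_ref)),
                       cfg, "reverse")
  expect_identical(rr$insert, tpl$product_ref)
})

test_that("reads missing a landmark are rejected with a typed reason", {
  no_ad <- paste0(bc$barcodes[1], LP, tpl$product_ref)
  expect_identical(extract_insert(no_ad, cfg, "forward")$reason,
                   "no_right_adapter")
  bad_lp <- paste0(bc$barcodes[1], "TTTTTTTTTTTTTTTTTTT", tpl$product_ref, AD)
  expect_identical(extract_insert(bad_lp, cfg, "forward")$reason,
                   "no_left_primer")
  expect_identical(extract_insert("ACGT", cfg, "forward")$reason,
                   "no_left_primer")
  # a barcode one edit away from every set member is rejected: matching is
  # exact by design
  mut <- bc$barcodes[1]
  substr(mut, 1, 1) <- setdiff(c("A", "C", "G", "T"), substr(mut, 1, 1))[1]
  expect_false(mut %in% bc$barcodes)
  near <- paste0(mut, LP, tpl$product_ref, AD)
  expect_identical(extract_insert(near, cfg, "forward")$reason, "bad_barcode")
})

test_that("the pair filter demands exact insert agreement", {
  a <- tpl$product_ref
  b <- a; substr(b, 30, 30) <- "A"
  expect_true(pair_filter(a, a))
  expect_false(pair_filter(a, b))
  expect_false(pair_filter(a, substr(a, 1, 70)))
})

test_that("demultiplexing matches ground truth and stats partition the input", {
  plate <- plate_design(data.frame(mn_uM = c(75, 800), mg_uM = 0, ca_uM = 0),
                        n_replicates = 2, reads_per_well = 300)
  sim <- simulate_plate(plate, load_preset("dpo4_paper"), tpl, seed = 13,
                        dimer_frac = 0.05)
  fc <- filter_config(plate$barcode_set)
  dx <- filter_and_demux(sim$fwd, sim$rev, fc, wells = plate$wells)
  expect_equal(sum(dx$stats$count), length(sim$fwd))
  # all primer-dimer truth reads are caught by the dimer filter
  truth_dimer <- sim$truth$read_id[sim$truth$is_primer_dimer]
  called_dimer <- dx$assign$read_id[dx$assign$outcome == "primer_dimer"]
  expect_setequal(called_dimer, truth_dimer)
  expect_equal(length(called_dimer) / length(sim$fwd), 0.05, tolerance = 0.1)
  # every accepted read routes to its true well
  acc <- dx$assign[dx$assign$outcome == "accepted", ]
  truth_map <- setNames(sim$truth$well_id, sim$truth$read_id)
  expect_identical(acc$well_id, unname(truth_map[acc$read_id]))
})

test_that("mate disagreement is rejected as pair_mismatch", {
  fwd <- paste0(bc$barcodes[1], LP, tpl$product_ref, AD)
  rev_ok <- revcomp(paste0(bc$barcodes[1], LP, tpl$product_ref))
  mut <- tpl$product_ref; substr(mut, 10, 10) <- "C"
  rev_bad <- revcomp(paste0(bc$barcodes[1], LP, mut))
  dx <- filter_and_demux(c(a = fwd, b = fwd), c(a = rev_ok, b = rev_bad), cfg)
  expect_equal(dx$stats$count[dx$stats$reason == "accepted"], 1)
  expect_equal(dx$stats$count[dx$stats$reason == "pair_mismatch"], 1)
})

test_that("empty input yields empty wells and zeroed stats", {
  dx <- filter_and_demux(character(0), character(0), cfg)
  expect_true(all(dx$stats$count == 0))
  expect_true(all(lengths(dx$wells) == 0))
})
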