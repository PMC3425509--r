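tpl <- bundled_template("original")
ref <- tpl$product_ref
t_pos <- which(tpl$template_ext_order == "T")

test_that("perfect reads tally zero errors and full totals", {
  tal <- tally_alignments(rep(ref, 10), tpl)
  expect_true(all(tal$per_position$n_err == 0))
  expect_true(all(tal$per_position$n_tot == 10))
  # all incorporations sit in the Watson-Crick cells
  expect_equal(sum(tal$transitions), 10 * 76)
  for (b in c("A", "C", "G", "T")) {
    wrong <- setdiff(c("A", "C", "G", "T"), chartr("ACGT", "TGCA", b))
    expect_true(all(tal$transitions[b, wrong] == 0))
  }
})

test_that("hand-placed errors are counted by position, base and transition", {
  p5 <- t_pos[1]                     # a template-T position
  bad <- ref; substr(bad, p5, p5) <- "G"
  tal <- tally_alignments(c(bad, bad, ref, ref), tpl)
  expect_equal(tal$per_position$n_err[p5], 2)
  expect_equal(tal$per_position$n_tot[p5], 4)
  expect_equal(tal$transitions["T", "G"], 2)
  expect_equal(sum(tal$per_position$n_err), 2)
  r <- misincorporation_rates(tal)
  expect_equal(r$per_position$rate[p5], 0.5)
})

test_that("gap columns count towards neither numerator nor denominator", {
  gapped <- ref
  substr(gapped, 10, 10) <- "-"
  tal <- tally_alignments(c(gapped, ref), tpl)
  expect_equal(tal$per_position$n_tot[10], 1)
  expect_equal(tal$per_position$n_err[10], 0)
  expect_equal(tal$per_position$n_tot[11], 2)
})

test_that("alignments of the wrong length are refused", {
  expect_error(tally_alignments(substr(ref, 1, 60), tpl), "outside")
})

test_that("transition rows normalise to wrong-dNTP distributions", {
  tal <- polyrec:::new_tally(76, tpl)
  tal$transitions["T", c("G", "C", "T")] <- c(30, 6, 4)
  tm <- transition_matrix(tal)
  expect_equal(unname(tm["T", c("G", "C", "T")]), c(0.75, 0.15, 0.10))
  expect_equal(sum(tm["T", ], na.rm = TRUE), 1)
  expect_true(is.na(tm["T", "A"]))          # Watson-Crick cell is not a row entry
  expect_true(all(is.na(tm["A", ])))        # rows without errors are omitted
})

test_that("replicate statistics follow the duplicate-well convention", {
  rs <- replicate_stats(c(0.010, 0.012), c("c1", "c1"))
  expect_equal(rs$mean, 0.011)
  expect_equal(rs$sem, 0.001)
  single <- replicate_stats(0.02, "c1")
  expect_equal(single$mean, 0.02)
  expect_true(is.na(single$sem))            # undefined with one well
  equal4 <- replicate_stats(rep(0.03, 4), rep("c1", 4))
  expect_equal(equal4$sem, 0)
})

test_that("noise floors recover the generator's substitution probability", {
  # a zero-error control gives floors of exactly zero
  clean <- tally_alignments(rep(ref, 5), tpl)
  nf0 <- noise_floor(list(clean, clean))
  expect_equal(nf0$mean_floor, 0)
  expect_equal(nf0$spatial_floor, 0)
  # Phusion control wells see only the 1e-3 synthesis noise floor
  plate <- plate_design(data.frame(mn_uM = 0, mg_uM = 7000, ca_uM = 0),
                        n_replicates = 2, reads_per_well = 2000,
                        preset_name = "phusion_control")
  out <- run_small_pipeline(plate, load_preset("phusion_control"), tpl,
                            seed = 17)
  nf <- noise_floor(out$quant$tallies)
  expect_equal(nf$mean_floor, 1e-3, tolerance = 0.25)
  expect_gt(nf$spatial_floor, nf$mean_floor)  # max over positions sits higher
  # floors do not depend on well ordering
  nf_rev <- noise_floor(base::rev(out$quant$tallies))
  expect_equal(nf_rev$mean_floor, nf$mean_floor)
  expect_equal(nf_rev$spatial_floor, nf$spatial_floor)
})
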