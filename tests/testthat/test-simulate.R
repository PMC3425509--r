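tpl <- bundled_template("original")

test_that("an error-free polymerase reproduces the product reference", {
  sim <- simulate_extension(tpl, flat_preset(0), cation_condition(), n = 20,
                            seed = 1, noise_sub_prob = 0)
  expect_true(all(sim$insert == tpl$product_ref))
  expect_true(all(sim$n_poly == 0))
  expect_true(all(sim$events == ""))
})

test_that("a rate-1 template-T channel writes G at every template T", {
  rows <- list(A = c(A = 1/3, C = 1/3, G = 1/3),
               C = c(A = 1/3, C = 1/3, T = 1/3),
               G = c(A = 1/3, G = 1/3, T = 1/3),
               T = c(C = 0, G = 1, T = 0))
  p <- polymerase_preset(
    "t_to_g", rate_params = list(A = list(r0 = 0), C = list(r0 = 0),
                                 G = list(r0 = 0), T = list(r0 = 1)),
    transition_rows = rows, truncation_prob = 0, indel_prob = 0,
    r_max = 1)
  sim <- simulate_extension(tpl, p, cation_condition(), n = 10, seed = 2,
                            noise_sub_prob = 0)
  t_pos <- which(tpl$template_ext_order == "T")
  for (s in sim$insert) {
    ch <- strsplit(s, "")[[1]]
    expect_true(all(ch[t_pos] == "G"))
    expect_identical(ch[-t_pos],
                     strsplit(tpl$product_ref, "")[[1]][-t_pos])
  }
})

test_that("Monte-Carlo per-base error frequencies match the analytic rates", {
  p <- load_preset("dpo4_paper")
  p$truncation_prob <- 0; p$indel_prob <- 0
  cond <- cation_condition(mn_uM = 400)
  n <- 10000
  sim <- simulate_extension(tpl, p, cond, n = n, seed = 7, noise_sub_prob = 0)
  cm <- matrix(unlist(strsplit(sim$insert, "")), nrow = n, byrow = TRUE)
  refc <- strsplit(tpl$product_ref, "")[[1]]
  mism <- t(cm) != refc
  for (b in c("A", "C", "G", "T")) {
    pos <- which(tpl$template_ext_order == b)
    r_hat <- mean(mism[pos, ])
    r <- rate_oracle(p, b, cond)
    se <- sqrt(r * (1 - r) / (n * length(pos)))
    # heterogeneity correlates errors within a read; allow 3 inflated SEs
    infl <- sqrt(1 + (length(pos) - 1) * r / p$heterogeneity_shape)
    expect_lt(abs(r_hat - r), 3 * se * infl + 1e-12)
  }
})

test_that("per-molecule event truth is conserved", {
  p <- load_preset("klenow_paper")
  cond <- cation_condition(mn_uM = 800)
  sim <- simulate_extension(tpl, p, cond, n = 2000, seed = 3,
                            noise_sub_prob = 1e-3)
  n_x <- vapply(strsplit(sim$events, ";"), function(ev)
    sum(grepl("^[0-9]+X", ev)), integer(1))
  n_n <- vapply(strsplit(sim$events, ";"), function(ev)
    sum(grepl("^[0-9]+N", ev)), integer(1))
  expect_identical(n_x, sim$n_poly)
  expect_identical(n_n, sim$n_noise)
  # events never exceed the realised molecule length (on indel-free reads,
  # where substitution positions stay in extension coordinates)
  no_indel <- !grepl("[0-9](I|D)", sim$events)
  pos <- lapply(strsplit(sim$events[no_indel], ";"), function(ev)
    as.integer(sub("[XN].*$", "", ev[nzchar(ev)])))
  expect_true(all(mapply(function(pp, l) length(pp) == 0 || max(pp) <= l,
                         pos, sim$length[no_indel])))
})

test_that("plates are bit-reproducible given the seed", {
  plate <- plate_design(data.frame(mn_uM = c(75, 800), mg_uM = 0, ca_uM = 0),
                        n_replicates = 1, reads_per_well = 50)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  s1 <- simulate_plate(plate, flat_preset(0.01), tpl, seed = 5, out_dir = d1)
  s2 <- simulate_plate(plate, flat_preset(0.01), tpl, seed = 5, out_dir = d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "reads_R1.fastq"))),
                   unname(tools::md5sum(file.path(d2, "reads_R1.fastq"))))
  expect_identical(unname(tools::md5sum(file.path(d1, "reads_R2.fastq"))),
                   unname(tools::md5sum(file.path(d2, "reads_R2.fastq"))))
  s3 <- simulate_plate(plate, flat_preset(0.01), tpl, seed = 6)
  expect_false(identical(s1$fwd, s3$fwd))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("a high-fidelity control plate carries only noise-floor errors", {
  plate <- plate_design(data.frame(mn_uM = 0, mg_uM = 7000, ca_uM = 0),
                        n_replicates = 2, reads_per_well = 400,
                        preset_name = "phusion_control")
  sim <- simulate_plate(plate, load_preset("phusion_control"), tpl, seed = 8)
  expect_true(all(sim$truth$n_poly_errors == 0))
  expect_gt(sum(sim$truth$n_noise_subs), 0)
})

test_that("the toy structure profile reflects self-complementarity", {
  homo <- template_spec("polyA", strrep("A", 40), 10)
  prof <- toy_structure_profile(homo)
  expect_equal(nrow(prof), homo$ext_len)
  expect_true(all(prof$s == 0))
  # perfect hairpin: stem pairs with itself, loop does not
  stem <- "GCGCGCGCGC"
  hp <- template_spec("hairpin",
                      paste0(stem, "AAAATTTTAAAA", revcomp(stem), "ACGTACGTAC"),
                      10)
  ph <- toy_structure_profile(hp)
  stem_score <- mean(ph$s[1:8])
  loop_score <- mean(ph$s[14:18])
  expect_gt(stem_score, loop_score)
  expect_true(all(ph$s >= 0 & ph$s <= 1))
})
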