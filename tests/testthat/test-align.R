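tpl <- bundled_template("original")
ref <- tpl$product_ref

test_that("identity scoring reproduces hand-computed scores", {
  expect_equal(global_align(ref, ref)$score, 76)
  sub1 <- ref; substr(sub1, 33, 33) <- setdiff(c("A", "C", "G", "T"),
                                               substr(ref, 33, 33))[1]
  expect_equal(global_align(sub1, ref)$score, 75)       # 75 matches, mismatch 0
  del1 <- paste0(substr(ref, 1, 40), substr(ref, 42, 76))
  expect_equal(global_align(del1, ref)$score, 65)       # 75 - gap open 10
  del2 <- paste0(substr(ref, 1, 40), substr(ref, 43, 76))
  expect_equal(global_align(del2, ref)$score, 62)       # 74 - 10 - 2
  # end gaps are scored: a 70-base abortive product pays the full tail gap
  expect_equal(global_align(substr(ref, 1, 70), ref)$score,
               70 - 10 - 2 * 5)
})

test_that("alignment scores agree with an exhaustive DP oracle on random 12-mers", {
  set.seed(41)
  for (i in 1:200) {
    a <- random_dna(1, sample(8:14, 1))
    b <- random_dna(1, 12)
    expect_equal(global_align(a, b)$score, gotoh_score(a, b),
                 info = paste(a, b))
  }
})

test_that("the batch aligner agrees with the DP oracle on realistic reads", {
  set.seed(42)
  reads <- character(30)
  for (i in seq_along(reads)) {
    x <- strsplit(ref, "")[[1]]
    nmut <- sample(0:3, 1)
    if (nmut > 0) {
      at <- sample(76, nmut)
      x[at] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
    }
    if (runif(1) < 0.3) x <- x[-sample(76, 1)]          # deletion
    if (runif(1) < 0.2) {
      at <- sample(length(x), 1)
      x <- append(x, sample(c("A", "C", "G", "T"), 1), at)  # insertion
    }
    reads[i] <- paste(x, collapse = "")
  }
  batch <- polyrec:::align_batch(reads, ref)
  oracle <- vapply(reads, gotoh_score, numeric(1), b = ref)
  expect_equal(batch$score, unname(oracle))
})

test_that("acceptance requires length >= 70 and score strictly > 60", {
  expect_true(accept_alignment(76, 76))
  expect_false(accept_alignment(69, 69))      # too short, whatever the score
  expect_false(accept_alignment(76, 60))      # boundary score rejected
  expect_true(accept_alignment(70, 60.5))
  p <- alignment_params()
  # a 76-mer with 16 mismatches scores exactly 60 and is rejected
  x <- strsplit(ref, "")[[1]]
  at <- seq(1, 76, by = 4)[1:16]
  x[at] <- chartr("ACGT", "TGCA", x[at])
  read16 <- paste(x, collapse = "")
  al <- global_align(read16, ref, p)
  expect_equal(al$score, 60)
  expect_false(accept_alignment(nchar(read16), al$score, p))
})

test_that("ambiguous bases score zero and are never counted", {
  withN <- ref; substr(withN, 10, 10) <- "N"
  expect_equal(global_align(withN, ref)$score, 75)
  tal <- tally_alignments(withN, tpl)
  expect_equal(tal$per_position$n_tot[10], 0)
  expect_equal(tal$per_position$n_err[10], 0)
  expect_equal(sum(tal$per_position$n_tot), 75)
})
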