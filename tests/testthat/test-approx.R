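test_that("hamming distance counts differing positions of equal-length strings", {
  expect_equal(hamming_distance("ACGT", "ACGT"), 0L)
  expect_equal(hamming_distance("AAAA", "TTTT"), 4L)
  expect_equal(hamming_distance("ACGT", "ACGA"), 1L)
  expect_equal(hamming_distance("acgt", "ACGA"), 1L)
  expect_error(hamming_distance("AC", "ACG"), "equal-length")
})

test_that("sliding-window search reports every window within budget", {
  h <- hamming_window_search("AAAA", "AT", max_mismatches = 1)
  expect_equal(h$hits$start, c(0L, 1L, 2L))
  expect_equal(h$hits$mismatch_count, c(1L, 1L, 1L))
  expect_equal(h$hits$mismatch_offsets, list(1L, 1L, 1L))

  h0 <- hamming_window_search("ACGACGACG", "ACGACG", 0)
  expect_identical(h0$hits$start, epm_search("ACGACGACG", "ACGACG")$hits$start)

  hid <- hamming_window_search("ACGT", "ACGT", 4)
  expect_equal(hid$hits$start, 0L)
  expect_equal(hid$hits$mismatch_count, 0L)
})

test_that("early abandon changes cost but never the hit set", {
  set.seed(11)
  for (i in 1:50) {
    inst <- rand_instance(ls_max = 400, lp_max = 25)
    eta <- sample(0:4, 1)
    full <- hamming_window_search(inst$seq, inst$pat, eta)
    fast <- hamming_window_search(inst$seq, inst$pat, eta,
                                  early_abandon = TRUE)
    expect_identical(full$hits, fast$hits)
    expect_lte(fast$stats$char_comparisons, full$stats$char_comparisons)
  }
})

test_that("mismatch-tolerant search reduces to exact search at zero budget", {
  o <- opsi_search("ACGACGACG", "ACGACG", 0)
  expect_equal(o$hits$start, c(0L, 3L))
  expect_equal(o$hits$mismatch_count, c(0L, 0L))
  set.seed(22)
  for (i in 1:50) {
    inst <- rand_instance(ls_max = 500, lp_max = 20)
    expect_identical(opsi_search(inst$seq, inst$pat, 0)$hits$start,
                     epm_search(inst$seq, inst$pat)$hits$start)
  }
})

test_that("degenerate budget at or above pattern length reports every window", {
  o <- opsi_search("AAAA", "AT", 2)
  expect_equal(o$hits$start, c(0L, 1L, 2L))
  o2 <- opsi_search("ACGT", "GG", 5)
  expect_equal(o2$hits$start, 0:2)
})

test_that("invalid budgets and empty patterns are rejected", {
  expect_error(opsi_search("ACGT", "AC", -1), "non-negative")
  expect_error(opsi_search("ACGT", "AC", 1.5), "non-negative")
  expect_error(opsi_search("ACGT", "", 1), "at least one residue")
  expect_error(hamming_window_search("ACGT", "", 1), "at least one residue")
})

test_that("every reported hit is sound and no exact hit is missed", {
  set.seed(33)
  opsi_n <- 0; oracle_n <- 0
  for (i in 1:200) {
    inst <- rand_instance(ls_max = 600, lp_max = 30)
    eta <- sample(0:5, 1)
    o <- opsi_search(inst$seq, inst$pat, eta)
    hw <- hamming_window_search(inst$seq, inst$pat, eta,
                                early_abandon = TRUE)
    e <- epm_search(inst$seq, inst$pat)

    # soundness: reported count equals true window distance and fits budget
    for (r in seq_len(nrow(o$hits))) {
      w <- substr(inst$seq, o$hits$start[r] + 1, o$hits$end[r])
      expect_equal(hamming_distance(w, inst$pat), o$hits$mismatch_count[r])
      expect_lte(o$hits$mismatch_count[r], eta)
    }
    # hits sorted, unique, and a subset of the exhaustive oracle
    expect_false(is.unsorted(o$hits$start, strictly = TRUE))
    expect_true(all(o$hits$start %in% hw$hits$start))
    # exact occurrences are never missed
    expect_true(all(e$hits$start %in%
                      o$hits$start[o$hits$mismatch_count == 0]))
    opsi_n <- opsi_n + nrow(o$hits)
    oracle_n <- oracle_n + nrow(hw$hits)
  }
  # completeness is measured, not guaranteed: report recall vs the oracle
  testthat::expect_gt(oracle_n, 0)
  message(sprintf("mismatch-tolerant search recall vs oracle: %.4f (%d/%d)",
                  opsi_n / oracle_n, opsi_n, oracle_n))
})
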