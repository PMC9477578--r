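test_that("pattern automaton transitions follow the prefix-suffix rule", {
  d <- build_dfa("AAC", alphabet = c("A", "C"))
  expect_equal(attr(d, "accept_state"), 3L)
  expect_equal(unname(d["2", "C"]), 3L)  # state 2 on 'C' -> accept state 3
  expect_equal(unname(d[1, "C"]), 0L)    # state 0 on a symbol != p_0 stays 0
  expect_equal(unname(d[1, "A"]), 1L)
  # accept state continues so repeated occurrences are found
  expect_equal(dfa_search("AACAAC", d)$hits$start, c(0L, 3L))
})

test_that("automaton scan finds exact occurrences", {
  expect_equal(dfa_search("AAAC", build_dfa("AAC"))$hits$start, 1L)
  expect_equal(dfa_search("ACGT", build_dfa("ACGT"))$hits$start, 0L)
  expect_equal(nrow(dfa_search("CCCC", build_dfa("AAC"))$hits), 0L)
})

test_that("symbols outside the automaton alphabet reset the scan", {
  d <- build_dfa("ACG", alphabet = "dna")
  expect_equal(dfa_search("ACNACGT", d)$hits$start, 3L)
  expect_equal(nrow(dfa_search("ACNG", d)$hits), 0L)
})

test_that("pattern symbols outside the declared alphabet are rejected", {
  expect_error(build_dfa("ACGT", alphabet = c("A", "C")), "outside")
})

test_that("automaton scan agrees with the linear matcher on random instances", {
  set.seed(44)
  for (i in 1:200) {
    inst <- rand_instance(ls_max = 500, lp_max = 20)
    d <- build_dfa(inst$pat, alphabet = "dna")
    expect_identical(dfa_search(inst$seq, d)$hits$start,
                     epm_search(inst$seq, inst$pat)$hits$start)
  }
})

test_that("bad-character table records rightmost occurrences", {
  expect_equal(bm_bad_char_table("ACG", "dna"),
               structure(c(A = 0L, C = 1L, G = 2L, T = -1L),
                         ops = 4 + 3))
  t2 <- bm_bad_char_table("ACGACG", "dna")
  expect_equal(unclass(t2)[c("A", "C", "G", "T")],
               c(A = 3L, C = 4L, G = 5L, T = -1L), ignore_attr = TRUE)
  t3 <- bm_bad_char_table("AAAA", "dna")
  expect_equal(unclass(t3)[c("A", "C", "G", "T")],
               c(A = 3L, C = -1L, G = -1L, T = -1L), ignore_attr = TRUE)
  # idempotent and sequence-independent by construction
  expect_identical(bm_bad_char_table("ACGACG", "dna"),
                   bm_bad_char_table("ACGACG", "dna"))
  expect_error(bm_bad_char_table("", "dna"), "at least one residue")
})

test_that("both preprocessing costs are linear and of comparable size", {
  set.seed(55)
  lps <- c(500L, 1000L, 2000L, 4000L)
  for (lp in lps) {
    p <- rand_string(lp)
    cs <- attr(compute_sbarc(p), "comparisons")
    cb <- attr(bm_bad_char_table(p, "dna"), "ops")
    expect_lte(cs, 2 * lp)
    expect_equal(cb, lp + 4)
    # same order of magnitude: within a small constant factor
    expect_lt(max(cs, cb) / min(cs, cb), 3)
  }
})
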