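test_that("random sequences are seeded, typed and uniform", {
  a <- random_sequence(50, "dna", seed = 9)
  b <- random_sequence(50, "dna", seed = 9)
  expect_identical(a$residues, b$residues)
  expect_false(identical(a$residues, random_sequence(50, "dna", seed = 10)$residues))
  expect_equal(random_sequence(0, "dna", seed = 1)$length, 0L)
  expect_error(random_sequence(-1, "dna", 1), "non-negative")

  # symbol frequencies at length 1e5 within the 99% binomial band of 0.25
  s <- random_sequence(1e5, "dna", seed = 123)
  freq <- table(strsplit(s$residues, "")[[1]]) / 1e5
  half_width <- qnorm(0.995) * sqrt(0.25 * 0.75 / 1e5)
  expect_true(all(abs(freq - 0.25) < half_width))

  p <- random_sequence(1000, "protein", seed = 3)
  expect_true(all(strsplit(p$residues, "")[[1]] %in%
                    alphabet_symbols("protein")))
})

test_that("planted occurrences carry exactly the requested substitutions", {
  pat <- "ACGTACGTACGTACGT"
  sp <- synthetic_spec(500, "dna", seed = 77,
                       plants = data.frame(pattern = pat,
                                           start = c(50, 200, 400),
                                           k = c(0, 2, 5)))
  gen <- plant_occurrences(sp)
  expect_equal(gen$sequence$length, 500L)
  for (r in seq_len(nrow(gen$truth))) {
    s <- gen$truth$start[r]
    w <- substr(gen$sequence$residues, s + 1, s + nchar(pat))
    expect_equal(hamming_distance(w, pat), gen$truth$k[r])
  }
  # exact plant is found by the exact matcher
  expect_true(50 %in% epm_search(gen$sequence, pat)$hits$start)
  # each plant is found by the exhaustive oracle at budget k
  for (r in seq_len(nrow(gen$truth))) {
    hw <- hamming_window_search(gen$sequence, pat, gen$truth$k[r])
    idx <- match(gen$truth$start[r], hw$hits$start)
    expect_false(is.na(idx))
    expect_equal(hw$hits$mismatch_count[idx], gen$truth$k[r])
  }
  # a plant with k = 3 is invisible to a budget of 2 at its own start
  sp3 <- synthetic_spec(300, "dna", seed = 5,
                        plants = data.frame(pattern = pat, start = 100, k = 3))
  g3 <- plant_occurrences(sp3)
  hw2 <- hamming_window_search(g3$sequence, pat, 2)
  expect_false(100 %in% hw2$hits$start)
})

test_that("invalid plantings are rejected", {
  p <- "ACGTACGT"
  expect_error(synthetic_spec(20, "dna", 1,
                              data.frame(pattern = p, start = 15, k = 0)),
               "outside")
  expect_error(synthetic_spec(100, "dna", 1,
                              data.frame(pattern = p, start = c(10, 14),
                                         k = c(0, 0))),
               "overlap")
  expect_error(synthetic_spec(100, "dna", 1,
                              data.frame(pattern = p, start = 10, k = 9)),
               "k <= pattern length")
})

test_that("average-pairwise-slope improvement matches analytic cases", {
  s1 <- data.frame(x = 1:4, cost = c(0, 10, 20, 30))
  expect_equal(pairwise_slope_improvement(s1, s1), 0)
  half <- data.frame(x = 1:4, cost = c(0, 5, 10, 15))
  expect_equal(pairwise_slope_improvement(half, s1), 50)
  slow <- data.frame(x = 1:3, cost = c(0, 10, 20))
  fast <- data.frame(x = 1:3, cost = c(0, 3, 6))
  expect_equal(pairwise_slope_improvement(fast, slow), 70)

  expect_error(pairwise_slope_improvement(fast, data.frame(x = 2:4, cost = 1:3)),
               "identical x grid")
  expect_error(pairwise_slope_improvement(data.frame(x = 1, cost = 1),
                                          data.frame(x = 1, cost = 1)),
               "at least 2 points")
  expect_error(pairwise_slope_improvement(data.frame(x = c(1, 1), cost = 1:2),
                                          data.frame(x = c(1, 1), cost = 1:2)),
               "strictly increasing")
})

test_that("benchmark runs are reproducible and reject unknown algorithms", {
  b1 <- run_benchmark("eta", seed = 2, repeats = 2, ls = 400, lp = 40,
                      etas = c(0, 5, 10))
  b2 <- run_benchmark("eta", seed = 2, repeats = 2, ls = 400, lp = 40,
                      etas = c(0, 5, 10))
  expect_identical(b1$comparisons, b2$comparisons)
  expect_true(all(diff(bench_series(b1, "opsi")$cost) >= 0))
  expect_error(run_benchmark("eta", algorithms = "quantum"), "unknown algorithm")

  bp <- run_benchmark("preproc", seed = 2, repeats = 1,
                      pattern_lengths = c(1000, 2000))
  expect_setequal(unique(bp$algorithm), c("sbarc", "badchar"))
  # both preprocessing costs grow linearly: comparable magnitude per point
  for (x in unique(bp$x)) {
    costs <- bp$comparisons[bp$x == x]
    expect_lt(max(costs) / min(costs), 3)
  }
})
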