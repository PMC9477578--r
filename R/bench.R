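#' Average-pairwise-slope improvement
#'
#' Cost-curve summary used to compare two matchers across a common grid of
#' input sizes: for each series the slopes between every two consecutive
#' points are computed and averaged; the improvement of the fast series over
#' the slow one is `100 * (mean_slow - mean_fast) / mean_slow` percent.
#'
#' @param fast,slow Data frames with columns `x` (strictly increasing, both
#'   on the identical grid) and `cost`, e.g. from [bench_series()].
#' @return Improvement percentage (positive when `fast` grows more slowly).
#' @examples
#' slow <- data.frame(x = 1:3, cost = c(0, 10, 20))
#' fast <- data.frame(x = 1:3, cost = c(0, 3, 6))
#' pairwise_slope_improvement(fast, slow)   # 70
#' @export
pairwise_slope_improvement <- function(fast, slow) {
  for (s in list(fast, slow)) {
    if (!is.data.frame(s) || !all(c("x", "cost") %in% names(s)) ||
        nrow(s) < 2L) {
      stop("each series needs columns x, cost and at least 2 points",
           call. = FALSE)
    }
    if (any(diff(s$x) <= 0)) stop("x must be strictly increasing",
                                  call. = FALSE)
    if (any(s$cost < 0)) stop("cost must be non-negative", call. = FALSE)
  }
  if (nrow(fast) != nrow(slow) || any(fast$x != slow$x)) {
    stop("series must share an identical x grid", call. = FALSE)
  }
  mean_fast <- mean(diff(fast$cost) / diff(fast$x))
  mean_slow <- mean(diff(slow$cost) / diff(slow$x))
  if (mean_slow == 0) {
    if (mean_fast == 0) return(0)
    stop("slow series has zero mean slope; improvement undefined",
         call. = FALSE)
  }
  100 * (mean_slow - mean_fast) / mean_slow
}

#' Extract one algorithm's cost series from a benchmark table
#'
#' @param bench Result of [run_benchmark()].
#' @param algorithm Algorithm label present in `bench`.
#' @param cost `"comparisons"` (default) or `"seconds"`.
#' @return Data frame with columns `x` and `cost`, ordered by `x`.
#' @export
bench_series <- function(bench, algorithm, cost = c("comparisons", "seconds")) {
  cost <- match.arg(cost)
  stopifnot(is.data.frame(bench), algorithm %in% bench$algorithm)
  b <- bench[bench$algorithm == algorithm, , drop = FALSE]
  b <- b[order(b$x), , drop = FALSE]
  data.frame(x = b$x, cost = b[[cost]])
}

#' Run a seeded comparison-count benchmark
#'
#' Reproducible benchmark harness over seeded uniform synthetic sequences.
#' Costs are character-comparison counts — a hardware-independent proxy for
#' running time — averaged over `repeats` independently generated inputs per
#' grid point; wall-clock seconds are recorded for information only. Three
#' grids are provided:
#'
#' * `"eta"`: mismatch-budget sweep — sequence of 6000 residues, pattern of
#'   200, budget 0 to 50 in steps of 10; algorithm `opsi`.
#' * `"length"`: sequence-length sweep (geometric, 1000 to 64000) at budget
#'   10 with a 200-residue pattern; algorithms `epm`, `opsi`, `hamming`.
#' * `"preproc"`: pattern-preprocessing sweep, pattern lengths 5000 to
#'   50000 in steps of 5000; compares the shift-table construction cost
#'   (character comparisons) with the Boyer-Moore bad-character table cost
#'   (table-write operations), both linear in the pattern length.
#'
#' All grid defaults can be overridden. Identical `(grid, seed, ...)` calls
#' return identical comparison counts.
#'
#' @param grid `"eta"`, `"length"` or `"preproc"`.
#' @param alphabet `"dna"` or `"protein"`.
#' @param seed Integer master seed; per-point input seeds are derived from it.
#' @param repeats Inputs generated (and averaged over) per grid point.
#' @param etas Budget values for the `"eta"` grid.
#' @param lengths Sequence lengths for the `"length"` grid.
#' @param pattern_lengths Pattern lengths for the `"preproc"` grid.
#' @param ls Fixed sequence length for the `"eta"` grid.
#' @param lp Fixed pattern length for the `"eta"` and `"length"` grids.
#' @param eta Fixed budget for the `"length"` grid.
#' @param algorithms Algorithm labels to run (defaults per grid as above).
#' @return Data frame with one row per `(algorithm, x)`: columns `grid`,
#'   `algorithm`, `x`, `comparisons` (mean), `seconds` (mean), `repeats`.
#' @examples
#' b <- run_benchmark("eta", seed = 1, repeats = 1, ls = 500, lp = 50,
#'                    etas = c(0, 5, 10))
#' bench_series(b, "opsi")
#' @export
run_benchmark <- function(grid = c("eta", "length", "preproc"),
                          alphabet = c("dna", "protein"), seed = 1L,
                          repeats = 5L,
                          etas = seq(0L, 50L, 10L),
                          lengths = 1000L * 2L^(0:6),
                          pattern_lengths = seq(5000L, 50000L, 5000L),
                          ls = 6000L, lp = 200L, eta = 10L,
                          algorithms = NULL) {
  grid <- match.arg(grid)
  alphabet <- match.arg(alphabet)
  seed <- as.integer(seed)
  if (is.null(algorithms)) {
    algorithms <- switch(grid,
      eta = "opsi",
      length = c("epm", "opsi", "hamming"),
      preproc = c("sbarc", "badchar"))
  }
  known <- c("epm", "naive", "opsi", "hamming", "dfa", "sbarc", "badchar")
  if (!all(algorithms %in% known)) {
    stop(sprintf("unknown algorithm(s): %s",
                 paste(setdiff(algorithms, known), collapse = ", ")),
         call. = FALSE)
  }

  xs <- switch(grid, eta = etas, length = lengths, preproc = pattern_lengths)
  rows <- list()
  for (xi in seq_along(xs)) {
    x <- xs[xi]
    for (alg in algorithms) {
      comp <- sec <- numeric(repeats)
      for (r in seq_len(repeats)) {
        # one derived seed per (grid point, repeat); same inputs for every
        # algorithm so the comparison is paired
        sd <- (seed * 97L + xi * 1009L + r * 131L) %% 2147483647L
        if (grid == "preproc") {
          patt <- random_sequence(x, alphabet, seed = sd)$residues
          t0 <- proc.time()[["elapsed"]]
          if (alg == "sbarc") {
            comp[r] <- attr(compute_sbarc(patt), "comparisons")
          } else {
            comp[r] <- attr(bm_bad_char_table(patt, alphabet), "ops")
          }
          sec[r] <- proc.time()[["elapsed"]] - t0
        } else {
          n <- if (grid == "length") x else ls
          e <- if (grid == "eta") x else eta
          sq <- random_sequence(n, alphabet, seed = sd)
          patt <- random_sequence(lp, alphabet, seed = sd + 1L)$residues
          t0 <- proc.time()[["elapsed"]]
          res <- switch(alg,
            epm = epm_search(sq, patt),
            naive = naive_search(sq, patt),
            opsi = opsi_search(sq, patt, e),
            hamming = hamming_window_search(sq, patt, e),
            dfa = dfa_search(sq, build_dfa(patt, alphabet)))
          sec[r] <- proc.time()[["elapsed"]] - t0
          comp[r] <- res$stats$char_comparisons
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        grid = grid, algorithm = alg, x = as.numeric(x),
        comparisons = mean(comp), seconds = mean(sec),
        repeats = repeats, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
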