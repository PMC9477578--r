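---
title: "Shift-table pattern matching: exact and mismatch-tolerant search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shift-table pattern matching: exact and mismatch-tolerant search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opsimatch)
```

## The problem

Biological sequences mutate. A motif searched for in a chromosome is often
present not verbatim but with a handful of point substitutions, so exact
string search misses it, while a full alignment is far more machinery than
the substitution-only question needs. `opsimatch` addresses the middle
ground: report every position where a pattern of length $l_p$ occurs in a
sequence of length $l_s$ with at most $\grave{e}$ substitutions (the hamming
error model — no insertions or deletions), and do so with a scan whose cost
grows like $O(l_s \cdot \grave{e})$ rather than the $O(l_s \cdot l_p)$ of
the sliding-window hamming scan.

## The shift table

Everything rests on the classic failure function. For a pattern $P =
p_0 \dots p_{l_p-1}$, the shift table stores at index $i$ the length of the
longest *proper* prefix of $P[0..i]$ that is also a suffix of $P[0..i]$:

```{r}
compute_sbarc("ACGACG")
```

When a scan has matched $j$ characters and then fails, the table entry at
$j-1$ names the longest pattern prefix already known to be present, so the
scan resumes there and never re-compares characters known to match. The
construction traverses the pattern once and performs at most $2 l_p$
character comparisons; a cubic brute-force reference (`lps_oracle()`) that
literally tries every prefix length is kept in the package and the two are
tested for equality exhaustively over every binary pattern up to length 12
and on random DNA patterns.

## Exact search

`epm_search()` is the KMP-style linear scan over that table: the sequence
index only ever moves forward, comparisons are bounded by $2 l_s$, and
after a full match the pattern index continues from the last table entry so
overlapping occurrences are all reported:

```{r}
epm_search("ACGACGACG", "ACGACG")
```

Two baselines frame it: `naive_search()` (every window, abandoned at its
first mismatch — up to $l_p(l_s - l_p + 1)$ comparisons on repetitive
input) and `dfa_search()` over a `build_dfa()` pattern automaton with
$l_p + 1$ states, one transition per character. The automaton is built by
the standard rule — from state $k$ on symbol $c$, go to $k + 1$ if $c =
p_k$, otherwise to the longest prefix-state that is a suffix of the
consumed text — with the accept state falling back through the shift table
so repeats are found. All three matchers are required by the test suite to
return identical hit sets on large random suites.

## Mismatch-tolerant search

`opsi_search()` extends the linear scan with an error budget
$\grave{e} \ge 0$. While characters match it behaves exactly like the exact
scan. At a mismatch with budget to spare, the mismatch is counted, the
coordinates of the *first* mismatch of the current alignment are recorded,
and the scan simply continues rightward. A window whose pattern index
reaches $l_p$ is reported with its mismatch count and offsets. When the
budget would be exceeded — or after reporting a hit that contained at least
one mismatch — the scan restarts from the recorded first mismatch: the
sequence index returns there and the pattern index resumes from the table
entry just before the first-mismatch position.

The restart is anchored at the *first* mismatch deliberately: every
character before it matched exactly, so the prefix-shift precondition of
the failure table holds there and the credited prefix is guaranteed
correct. Two edge cases are worth stating:

* first mismatch at pattern index 0 — there is no "entry before it"; the
  scan advances one position and starts fresh, mirroring the `j == 0`
  branch of the exact scan. With $\grave{e} = 0$ this makes the matcher
  reduce *identically* to `epm_search()`, which the suite asserts.
* $\grave{e} \ge l_p$ — every window trivially qualifies, so the matcher
  short-circuits to reporting every window start directly.

At a restart the error count and the recorded mismatch are fully cleared,
including when the resumed pattern prefix overlaps previously matched text;
the prefix credited by the shift table is mismatch-free by construction, so
a cleared counter is the correct state for it.

### Soundness, completeness, and what is asserted

Every reported window is re-verified at report time by direct comparison
against the pattern, so a hit's `mismatch_count` always equals the true
hamming distance of its window and never exceeds the budget (soundness is
self-certifying; the re-check is bookkeeping and is excluded from the
comparison counters). Hits are deduplicated and sorted.

Completeness is a different matter. The restart policy can in principle
skip a window that the exhaustive scan would report, and we know of no
proof that it cannot. The package therefore treats
`hamming_window_search()` — every window, every position, complete by
construction — as the oracle: the suite asserts that the tolerant matcher's
hits are a sound subset of the oracle's and that no exact occurrence is
ever missed, and it *measures* recall against the oracle (printed in the
test log, around 97–98% on uniform random DNA at $\grave{e} \le 5$) rather
than asserting 100%. Users who need guaranteed completeness at higher cost
should use `hamming_window_search()`.

## The synthetic generator

`random_sequence()` draws i.i.d. uniform symbols over the four nucleotides
or the twenty standard amino acids, fully determined by `(length, alphabet,
seed)`. `plant_occurrences()` emulates point mutation: it copies a pattern
into chosen non-overlapping windows of the background and applies exactly
$k$ substitutions at distinct random offsets, each changing the symbol, so
the planted window's hamming distance to the pattern is exactly $k$ by
construction and the returned truth table is exact.

What uniform background does *not* emulate: real genomic composition bias,
repeats, low-complexity regions, or homopolymer runs. Comparison counts on
repetitive real sequence will differ (the naive matcher in particular
degrades there); the passing tests certify algorithmic correctness and the
scaling behaviour on uniform material, not absolute performance on any
particular genome.

## Benchmark design

Wall-clock timings of string matchers are machine- and interpreter-specific,
so the harness's asserted metric is the count of character comparisons — an
exact, hardware-independent cost proxy incremented once per character-pair
equality test inside each scanner; seconds are recorded for information
only. `run_benchmark()` provides three seeded grids, each point averaged
over 5 independently generated inputs:

* **budget sweep** — sequence 6000, pattern 200, $\grave{e} \in \{0, 10,
  \dots, 50\}$: tolerant-scan cost must grow linearly in the budget
  (straight-line fit, $R^2 \ge 0.9$) and stay below
  $(\grave{e}+1) \cdot 2 l_s$ plus a small constant.
* **length sweep** — budget 10, pattern 200, sequence length geometric
  $1000 \cdot 2^{0..6}$ (the sweep values are an artifact default chosen to
  cover two decades): cost linear in $l_s$.
* **preprocessing sweep** — pattern lengths 5000..50000: shift-table
  construction comparisons against the Boyer–Moore bad-character table's
  write operations (`bm_bad_char_table()`, the bad-character half only —
  the good-suffix rule is out of scope). Both are linear in $l_p$ and stay
  within a small constant factor of one another.

The summary statistic for comparing two matchers across a sweep is the
**average pairwise slope improvement**: average the slopes between every
two consecutive points of each cost curve, then report
$100 (\bar{s}_{slow} - \bar{s}_{fast}) / \bar{s}_{slow}$ percent
(`pairwise_slope_improvement()`, unit-tested against analytic 0%, 50% and
70% cases). On the length sweep the tolerant matcher's improvement over the
sliding-window hamming baseline is asserted to be strictly positive for
both alphabets; its magnitude depends on the cost proxy and the baseline
variant, so no particular percentage is asserted.

The hamming baseline scans each window in full by default — the
$O(l_s \cdot l_p)$ formulation — because that is the formulation the
tolerant matcher is designed to beat; an `early_abandon` option stops a
window once the budget is exceeded (identical hit set, different cost) and
is what the correctness tests use to keep the oracle cheap.

```{r}
b <- run_benchmark("length", seed = 1, repeats = 2,
                   lengths = c(1000, 2000, 4000, 8000))
pairwise_slope_improvement(bench_series(b, "opsi"),
                           bench_series(b, "hamming"))
```

## Numerical and interface conventions

* All coordinates are 0-based, half-open `[start, end)`; BED output follows
  the same convention natively, and `--one-based` on the command line
  offsets display only.
* All residues are case-folded to uppercase on input (FASTA uses lowercase
  for masking). Under `alphabet = "auto"` any observed symbol is a legal
  residue that matches only itself; ambiguity codes such as `N` are *not*
  wildcards.
* Multi-record FASTA inputs are searched record by record; hits never span
  records.
* An empty pattern is an error everywhere; a pattern longer than the
  sequence yields an empty result, not an error.

## Problem sizes in the shipped tests

The suite validates the exact matchers on 1000 random instances
($l_s \le 2000$, $l_p \le 50$), the tolerant matcher on 500 instances
($l_s \le 1000$, $l_p \le 30$, $\grave{e} \le 5$), the shift table
exhaustively over all binary patterns up to length 12, and the benchmark
grids at the sizes listed above. These sizes were chosen as the smallest
that exercise every code path and scaling regime; all quantities the
vignette cites (recall, improvement percentages) are computed by the suite
itself at run time.
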