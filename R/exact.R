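#' Exact pattern matching with a linear scan
#'
#' KMP-style exact matcher: the sequence is scanned once, left to right; the
#' sequence index never moves backward. On a mismatch the pattern index
#' falls back through the shift table (see [compute_sbarc()]) so characters
#' already known to match are not re-compared; after a full match the scan
#' continues from the table entry of the last pattern index, so overlapping
#' occurrences are reported. Character comparisons are bounded by
#' `2 * l_s`.
#'
#' @param seq Sequence string or [as_sequence()] object.
#' @param pat Pattern string or [pattern()] object.
#' @return A `search_result`: `$hits` (data frame with 0-based half-open
#'   `start`/`end`, `mismatch_count` all zero for exact search),
#'   `$stats` (`char_comparisons`, `window_shifts`).
#' @examples
#' epm_search("ACGACGACG", "ACGACG")$hits$start   # 0 3
#' @export
epm_search <- function(seq, pat) {
  seq <- as_sequence(seq)
  pat <- pattern(pat)
  if (pat$length > seq$length) {
    return(new_search_result(integer(0), pat$length, "epm", 0, 0,
                             monotone = TRUE))
  }
  sv <- as.integer(compute_sbarc(pat))
  res <- epm_cpp(seq$residues, pat$residues, sv)
  new_search_result(res$starts, pat$length, "epm",
                    res$comparisons, res$shifts, monotone = res$monotone)
}

#' Naive exact matching
#'
#' Brute-force baseline: every window start from 0 to `l_s - l_p` is
#' examined and the window is compared character by character until its
#' first mismatch. `window_shifts` counts windows examined
#' (`l_s - l_p + 1` for a full scan); comparisons can reach
#' `l_p * (l_s - l_p + 1)` on repetitive inputs.
#'
#' @inheritParams epm_search
#' @return A `search_result` as in [epm_search()].
#' @examples
#' naive_search("ACGACGACG", "ACGACG")$hits$start   # 0 3
#' @export
naive_search <- function(seq, pat) {
  seq <- as_sequence(seq)
  pat <- pattern(pat)
  if (pat$length > seq$length) {
    return(new_search_result(integer(0), pat$length, "naive", 0, 0))
  }
  res <- naive_cpp(seq$residues, pat$residues)
  new_search_result(res$starts, pat$length, "naive",
                    res$comparisons, res$shifts)
}
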