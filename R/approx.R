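#' Hamming distance between equal-length strings
#'
#' Number of positions at which two equal-length strings differ — the
#' substitution-only error model. Comparison is case-folded to uppercase.
#'
#' @param a,b Strings of equal length.
#' @return Integer count of differing positions.
#' @examples
#' hamming_distance("ACGT", "ACGA")   # 1
#' @export
hamming_distance <- function(a, b) {
  stopifnot(is.character(a), is.character(b),
            length(a) == 1L, length(b) == 1L)
  if (nchar(a) != nchar(b)) {
    stop("hamming distance requires equal-length strings", call. = FALSE)
  }
  sum(charToRaw(toupper(a)) != charToRaw(toupper(b)))
}

#' Sliding-window hamming search
#'
#' Examines every window start from 0 to `l_s - l_p` and reports each window
#' whose hamming distance to the pattern is at most `max_mismatches`. This
#' exhaustive scan is complete by construction and serves as the correctness
#' oracle for [opsi_search()]. By default each window is compared in full
#' (the `O(l_s * l_p)` baseline); `early_abandon = TRUE` drops a window as
#' soon as its mismatch count exceeds the budget, which changes the
#' comparison count but never the hit set.
#'
#' @inheritParams epm_search
#' @param max_mismatches Non-negative substitution budget per occurrence.
#' @param early_abandon Stop scanning a window once the budget is exceeded.
#' @return A `search_result`; `$hits` carries `mismatch_count` and 0-based
#'   pattern-relative `mismatch_offsets` per hit.
#' @examples
#' hamming_window_search("AAAA", "AT", max_mismatches = 1)$hits$start  # 0 1 2
#' @export
hamming_window_search <- function(seq, pat, max_mismatches,
                                  early_abandon = FALSE) {
  seq <- as_sequence(seq)
  pat <- pattern(pat)
  eta <- check_eta(max_mismatches)
  if (pat$length > seq$length) {
    return(new_search_result(integer(0), pat$length, "hamming", 0, 0))
  }
  res <- hamming_window_cpp(seq$residues, pat$residues, eta,
                            isTRUE(early_abandon))
  new_search_result(res$starts, pat$length, "hamming",
                    res$comparisons, res$shifts,
                    counts = res$counts, offsets = res$offsets)
}

#' Mismatch-tolerant pattern search with shift-table restarts
#'
#' Approximate matcher tolerating up to `max_mismatches` substitutions per
#' occurrence. The scan proceeds as in [epm_search()]; a mismatch with spare
#' budget is counted and consumed and the scan continues rightward, with the
#' coordinates of the first mismatch of the current alignment recorded. When
#' the pattern index reaches `l_p` the window is reported with its mismatch
#' count and offsets. When the budget would be exceeded — or after reporting
#' a hit that contained at least one mismatch — the scan restarts: the
#' sequence index returns to the first-mismatch position and the pattern
#' index resumes from the shift-table entry just before the first-mismatch
#' pattern index (all characters before the first mismatch matched exactly,
#' so the prefix-shift precondition holds there). After an exact hit the
#' scan continues KMP-style without moving the sequence index. With
#' `max_mismatches = 0` the result is identical to [epm_search()].
#'
#' Every reported hit is re-verified by direct window comparison at report
#' time, so `mismatch_count` always equals the true hamming distance of the
#' window; this bookkeeping is not included in `char_comparisons`, which
#' counts scan comparisons only. Hits are sorted and deduplicated. When
#' `max_mismatches >= l_p` every window trivially qualifies and all window
#' starts are returned directly.
#'
#' @inheritParams hamming_window_search
#' @return A `search_result` as in [hamming_window_search()].
#' @examples
#' opsi_search("ACGACGACG", "ACGACG", max_mismatches = 0)$hits$start  # 0 3
#' @export
opsi_search <- function(seq, pat, max_mismatches) {
  seq <- as_sequence(seq)
  pat <- pattern(pat)
  eta <- check_eta(max_mismatches)
  if (pat$length > seq$length) {
    return(new_search_result(integer(0), pat$length, "opsi", 0, 0))
  }
  if (eta >= pat$length) {
    # degenerate budget: every window qualifies
    res <- hamming_window_cpp(seq$residues, pat$residues, eta, FALSE)
    return(new_search_result(res$starts, pat$length, "opsi",
                             res$comparisons, res$shifts,
                             counts = res$counts, offsets = res$offsets))
  }
  sv <- as.integer(compute_sbarc(pat))
  res <- opsi_cpp(seq$residues, pat$residues, sv, eta)
  new_search_result(res$starts, pat$length, "opsi",
                    res$comparisons, res$shifts,
                    counts = res$counts, offsets = res$offsets)
}

check_eta <- function(max_mismatches) {
  if (!is.numeric(max_mismatches) || length(max_mismatches) != 1L ||
      is.na(max_mismatches) || max_mismatches < 0 ||
      max_mismatches != round(max_mismatches)) {
    stop("max_mismatches must be a single non-negative integer",
         call. = FALSE)
  }
  as.integer(max_mismatches)
}
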