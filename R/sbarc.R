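#' Shift table construction (failure function)
#'
#' Builds the per-index shift table for a pattern: entry `i` (0-based) is the
#' length of the longest proper prefix of `pattern[0..i]` that is also a
#' suffix of `pattern[0..i]`. On a mismatch during a scan this value tells
#' the matcher which pattern index to resume from, so characters already
#' known to match are never re-compared. The pattern is traversed once; the
#' construction performs at most `2 * l_p` character comparisons (available
#' as `attr(x, "comparisons")`).
#'
#' @param pat Pattern string or [pattern()] object.
#' @return Integer vector of length `l_p` with class `sbarc_table`;
#'   attributes `pattern` (the residues) and `comparisons` (character
#'   comparisons spent building it).
#' @examples
#' compute_sbarc("ACGACG")   # 0 0 0 1 2 3
#' @seealso [lps_oracle()] for the brute-force reference construction.
#' @export
compute_sbarc <- function(pat) {
  pat <- pattern(pat)
  res <- sbarc_cpp(pat$residues)
  structure(res$values, class = "sbarc_table",
            pattern = pat$residues, comparisons = res$comparisons)
}

#' Brute-force shift-table reference
#'
#' Independent reference for [compute_sbarc()]: for each index `i` it tries
#' every proper prefix length `k` from `i` down to 0 and keeps the largest
#' `k` whose prefix equals the suffix ending at `i`. Cubic in the pattern
#' length; intended for validation, not production use.
#'
#' @inheritParams compute_sbarc
#' @return `sbarc_table` as in [compute_sbarc()] (without a comparison count).
#' @examples
#' lps_oracle("AAAA")   # 0 1 2 3
#' @export
lps_oracle <- function(pat) {
  pat <- pattern(pat)
  p <- pat$residues
  n <- pat$length
  values <- integer(n)
  for (i in seq_len(n) - 1L) {
    for (k in seq(i, 0L)) {
      if (k == 0L) { values[i + 1L] <- 0L; break }
      if (substr(p, 1L, k) == substr(p, i - k + 2L, i + 1L)) {
        values[i + 1L] <- k
        break
      }
    }
  }
  structure(values, class = "sbarc_table", pattern = p)
}

#' @export
print.sbarc_table <- function(x, ...) {
  pat <- attr(x, "pattern")
  cat(sprintf("<shift table> pattern %s\n", pat))
  print(data.frame(index = seq_along(x) - 1L,
                   residue = strsplit(pat, "")[[1]],
                   shift = as.integer(x)),
        row.names = FALSE)
  invisible(x)
}

#' @export
format.sbarc_table <- function(x, ...) format(as.integer(x), ...)
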