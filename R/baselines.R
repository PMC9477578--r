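#' Build the pattern-matching automaton
#'
#' Deterministic finite automaton with `l_p + 1` states `q_0 .. q_{l_p}`:
#' state `k` means the last `k` characters consumed equal the pattern's
#' first `k`. From state `k` on symbol `c` the next state is `k + 1` when
#' `c` equals the pattern's k-th residue, otherwise the longest state `j`
#' such that the length-`j` pattern prefix is a suffix of the consumed text
#' — computed in `O(l_p * |alphabet|)` via the shift table. The accept
#' state `l_p` falls back through the shift table too, so repeated and
#' overlapping occurrences are all found.
#'
#' @inheritParams epm_search
#' @param alphabet Symbol set for the transition table: `"dna"`,
#'   `"protein"`, a character vector of symbols, or `NULL` to use the
#'   pattern's declared set. Must cover every pattern symbol.
#' @return A `pattern_dfa`: transition matrix of dimension
#'   `(l_p + 1) x |alphabet|` (entries are next states), with attributes
#'   `pattern`, `sigma`, `accept_state`.
#' @examples
#' d <- build_dfa("AAC", alphabet = c("A", "C"))
#' attr(d, "accept_state")
#' @export
build_dfa <- function(pat, alphabet = NULL) {
  pat <- pattern(pat)
  sigma <- resolve_sigma(alphabet, pat)
  residues <- strsplit(pat$residues, "")[[1]]
  bad <- setdiff(unique(residues), sigma)
  if (length(bad) > 0L) {
    stop(sprintf("pattern symbols outside the automaton alphabet: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  lp <- pat$length
  ns <- length(sigma)
  trans <- matrix(0L, nrow = lp + 1L, ncol = ns,
                  dimnames = list(as.character(0:lp), sigma))
  # standard prefix-automaton construction: X shadows the failure state
  trans[1L, residues[1L]] <- 1L
  X <- 0L
  if (lp > 1L) {
    for (k in 1L:(lp - 1L)) {
      trans[k + 1L, ] <- trans[X + 1L, ]
      trans[k + 1L, residues[k + 1L]] <- k + 1L
      X <- trans[X + 1L, residues[k + 1L]]
    }
  }
  sv <- as.integer(compute_sbarc(pat))
  trans[lp + 1L, ] <- trans[sv[lp] + 1L, ]  # continue after accept
  structure(trans, class = "pattern_dfa", pattern = pat$residues,
            sigma = sigma, accept_state = lp)
}

#' @export
print.pattern_dfa <- function(x, ...) {
  cat(sprintf("<pattern automaton> pattern %s, %d states, alphabet {%s}\n",
              attr(x, "pattern"), nrow(x),
              paste(attr(x, "sigma"), collapse = ",")))
  invisible(x)
}

#' Exact search by automaton scan
#'
#' Runs the sequence through a [build_dfa()] automaton, one state transition
#' per character; a start index is emitted each time the accept state is
#' entered. Symbols outside the automaton's alphabet reset to state 0: they
#' can never be part of a match.
#'
#' @inheritParams epm_search
#' @param dfa A `pattern_dfa` from [build_dfa()].
#' @return A `search_result`; `window_shifts` is not meaningful for the
#'   automaton scan and is reported as the number of characters consumed.
#' @examples
#' dfa_search("AAAC", build_dfa("AAC"))$hits$start   # 1
#' @export
dfa_search <- function(seq, dfa) {
  stopifnot(inherits(dfa, "pattern_dfa"))
  seq <- as_sequence(seq)
  sigma <- attr(dfa, "sigma")
  lp <- attr(dfa, "accept_state")
  chars <- strsplit(seq$residues, "")[[1]]
  codes <- match(chars, sigma, nomatch = 0L)
  starts <- dfa_search_cpp(codes, unclass(dfa), lp)
  new_search_result(starts, lp, "dfa",
                    comparisons = seq$length, shifts = seq$length)
}

#' Boyer-Moore bad-character table
#'
#' Preprocessing half of the Boyer-Moore bad-character heuristic: for each
#' alphabet symbol, the rightmost 0-based index at which it occurs in the
#' pattern, or -1 if absent. One left-to-right pass, `O(l_p + |alphabet|)`.
#'
#' @inheritParams build_dfa
#' @return Named integer vector over the alphabet; attribute `ops` records
#'   the number of table-write operations spent (initialisation plus one per
#'   pattern character), the preprocessing cost proxy.
#' @examples
#' bm_bad_char_table("ACG")   # A=0 C=1 G=2 T=-1
#' @export
bm_bad_char_table <- function(pat, alphabet = NULL) {
  pat <- pattern(pat)
  sigma <- resolve_sigma(alphabet, pat)
  tab <- structure(rep(-1L, length(sigma)), names = sigma)
  residues <- strsplit(pat$residues, "")[[1]]
  known <- residues %in% sigma
  tab[residues[known]] <- which(known) - 1L  # rightmost write wins
  structure(tab, ops = length(sigma) + pat$length)
}

resolve_sigma <- function(alphabet, pat) {
  if (is.null(alphabet)) {
    if (pat$alphabet == "auto") pat$sigma else alphabet_symbols(pat$alphabet)
  } else if (is.character(alphabet) && length(alphabet) == 1L &&
             alphabet %in% c("dna", "protein")) {
    alphabet_symbols(alphabet)
  } else if (is.character(alphabet)) {
    sort(unique(toupper(alphabet)))
  } else {
    stop("alphabet must be NULL, a name, or a character vector",
         call. = FALSE)
  }
}
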