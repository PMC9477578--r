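#' Seeded uniform random sequence
#'
#' Draws i.i.d. uniform symbols from the chosen alphabet. The same
#' `(length, alphabet, seed)` always yields the same sequence; the caller's
#' RNG state is left untouched.
#'
#' @param length Target sequence length (>= 0).
#' @param alphabet `"dna"`, `"protein"` or a character vector of symbols.
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @param id Record identifier for the result.
#' @return An [as_sequence()] object.
#' @examples
#' random_sequence(10, "dna", seed = 1)
#' @export
random_sequence <- function(length, alphabet = "dna", seed = NULL,
                            id = "synthetic") {
  if (!is.numeric(length) || length(length) != 1L || is.na(length) ||
      length < 0 || length != round(length)) {
    stop("length must be a single non-negative integer", call. = FALSE)
  }
  sigma <- resolve_sigma(alphabet, pattern("A"))
  res <- with_seed(seed, {
    if (length == 0) "" else
      paste(sample(sigma, length, replace = TRUE), collapse = "")
  })
  as_sequence(res, id)
}

#' Specification for a synthetic sequence with planted occurrences
#'
#' Describes a uniform random background with copies of a pattern planted at
#' known starts, each carrying an exact number of substitutions — the
#' substitution-only mutation model. Plants must lie within the sequence and
#' must not overlap one another.
#'
#' @param length Background sequence length.
#' @param alphabet `"dna"` or `"protein"`.
#' @param seed Integer seed driving both background and mutations.
#' @param plants Data frame (or list coercible to one) with columns
#'   `pattern`, `start` (0-based), `k` (substitution count, `0 <= k <= l_p`).
#' @return A `synthetic_spec` list.
#' @examples
#' synthetic_spec(100, "dna", seed = 1,
#'                plants = data.frame(pattern = "ACGTACGT", start = 10, k = 2))
#' @export
synthetic_spec <- function(length, alphabet = c("dna", "protein"), seed,
                           plants = NULL) {
  alphabet <- match.arg(alphabet)
  if (is.null(plants)) {
    plants <- data.frame(pattern = character(0), start = integer(0),
                         k = integer(0))
  }
  plants <- as.data.frame(plants, stringsAsFactors = FALSE)
  stopifnot(all(c("pattern", "start", "k") %in% names(plants)))
  plants$pattern <- toupper(plants$pattern)
  plants$start <- as.integer(plants$start)
  plants$k <- as.integer(plants$k)
  lp <- nchar(plants$pattern)
  if (any(plants$start < 0 | plants$start + lp > length)) {
    stop("planted window outside the sequence", call. = FALSE)
  }
  if (any(plants$k < 0 | plants$k > lp)) {
    stop("substitution count must satisfy 0 <= k <= pattern length",
         call. = FALSE)
  }
  if (nrow(plants) > 1L) {
    ord <- order(plants$start)
    s <- plants$start[ord]; e <- s + lp[ord]
    if (any(s[-1L] < e[-length(e)])) {
      stop("planted windows must not overlap", call. = FALSE)
    }
  }
  structure(list(length = as.integer(length), alphabet = alphabet,
                 seed = as.integer(seed), plants = plants),
            class = "synthetic_spec")
}

#' Generate a sequence with planted mutated occurrences
#'
#' Draws the uniform background, then copies each planted pattern into its
#' window and applies exactly `k` substitutions at distinct seeded-random
#' offsets, each substitution changing the symbol to a different one. The
#' returned truth table records the planted start and the exact hamming
#' distance of the planted window to the pattern.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `sequence` (an [as_sequence()] object) and `truth`
#'   (data frame: `start`, `k`, `pattern`).
#' @examples
#' sp <- synthetic_spec(60, "dna", seed = 7,
#'                      plants = data.frame(pattern = "ACGTACGT",
#'                                          start = 20, k = 1))
#' plant_occurrences(sp)$truth
#' @export
plant_occurrences <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  sigma <- alphabet_symbols(spec$alphabet)
  with_seed(spec$seed, {
    chars <- if (spec$length == 0) character(0) else
      sample(sigma, spec$length, replace = TRUE)
    for (r in seq_len(nrow(spec$plants))) {
      patt <- strsplit(spec$plants$pattern[r], "")[[1]]
      s <- spec$plants$start[r]
      k <- spec$plants$k[r]
      window <- patt
      if (k > 0) {
        offs <- sample.int(length(patt), k)  # distinct offsets
        for (o in offs) {
          window[o] <- sample(setdiff(sigma, window[o]), 1L)
        }
      }
      chars[(s + 1L):(s + length(patt))] <- window
    }
    list(
      sequence = as_sequence(paste(chars, collapse = ""), "synthetic"),
      truth = data.frame(start = spec$plants$start, k = spec$plants$k,
                         pattern = spec$plants$pattern,
                         stringsAsFactors = FALSE)
    )
  })
}
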