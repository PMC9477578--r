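#' Built-in alphabets
#'
#' Symbol sets used for validation and synthesis: `dna` is the four
#' nucleotides, `protein` the twenty standard one-letter amino-acid codes.
#'
#' @param name `"dna"` or `"protein"`.
#' @return Character vector of single symbols.
#' @examples
#' alphabet_symbols("dna")
#' @export
alphabet_symbols <- function(name = c("dna", "protein")) {
  name <- match.arg(name)
  switch(name,
    dna = c("A", "C", "G", "T"),
    protein = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  )
}

#' Construct a search pattern
#'
#' Normalises a query string to uppercase and attaches its alphabet. With
#' `alphabet = "auto"` the symbol set is inferred from the residues observed,
#' so unusual symbols (ambiguity codes, gaps) are legal residues that simply
#' never match anything but themselves. With `"dna"` or `"protein"` residues
#' outside the declared set are an error.
#'
#' @param x Single non-empty string (or an existing `opsi_pattern`).
#' @param alphabet `"auto"`, `"dna"` or `"protein"`.
#' @return An `opsi_pattern`: list with `residues`, `length`, `alphabet`,
#'   `sigma` (the declared symbol set).
#' @examples
#' p <- pattern("acgACG", "dna")
#' p$residues
#' @export
pattern <- function(x, alphabet = c("auto", "dna", "protein")) {
  if (inherits(x, "opsi_pattern")) return(x)
  alphabet <- match.arg(alphabet)
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop("pattern must be a single string", call. = FALSE)
  }
  residues <- toupper(x)
  if (nchar(residues) < 1L) {
    stop("pattern must contain at least one residue", call. = FALSE)
  }
  symbols <- unique(strsplit(residues, "")[[1]])
  if (alphabet == "auto") {
    sigma <- sort(symbols)
  } else {
    sigma <- alphabet_symbols(alphabet)
    bad <- setdiff(symbols, sigma)
    if (length(bad) > 0L) {
      stop(sprintf("pattern contains symbols outside the %s alphabet: %s",
                   alphabet, paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  structure(
    list(residues = residues, length = nchar(residues),
         alphabet = alphabet, sigma = sigma),
    class = "opsi_pattern"
  )
}

#' @rdname pattern
#' @export
as_pattern <- function(x, alphabet = "auto") pattern(x, alphabet)

#' @export
print.opsi_pattern <- function(x, ...) {
  res <- x$residues
  if (nchar(res) > 60) res <- paste0(substr(res, 1, 57), "...")
  cat(sprintf("<pattern> %s  (length %d, alphabet %s)\n",
              res, x$length, x$alphabet))
  invisible(x)
}

#' Construct a subject sequence
#'
#' @param x Single string of residues (case-folded to uppercase), or an
#'   existing `opsi_sequence`.
#' @param id Record identifier.
#' @return An `opsi_sequence`: list with `id`, `residues`, `length`.
#' @examples
#' as_sequence("acgtacgt", "rec1")
#' @export
as_sequence <- function(x, id = "seq") {
  if (inherits(x, "opsi_sequence")) return(x)
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop("sequence must be a single string", call. = FALSE)
  }
  residues <- toupper(x)
  structure(
    list(id = as.character(id), residues = residues,
         length = nchar(residues)),
    class = "opsi_sequence"
  )
}

#' @export
print.opsi_sequence <- function(x, ...) {
  res <- x$residues
  if (nchar(res) > 60) res <- paste0(substr(res, 1, 57), "...")
  cat(sprintf("<sequence> %s  %s  (%d residues)\n", x$id, res, x$length))
  invisible(x)
}

# internal: bundle hits + instrumentation the way every matcher returns them
new_search_result <- function(starts, lp, algorithm, comparisons, shifts,
                              counts = NULL, offsets = NULL,
                              monotone = NA) {
  n <- length(starts)
  if (is.null(counts)) counts <- integer(n)
  if (is.null(offsets)) offsets <- rep(list(integer(0)), n)
  hits <- data.frame(
    start = as.integer(starts),
    end = as.integer(starts) + as.integer(lp),
    mismatch_count = as.integer(counts),
    stringsAsFactors = FALSE
  )
  hits$mismatch_offsets <- lapply(offsets, as.integer)
  structure(
    list(
      hits = hits,
      stats = structure(
        list(char_comparisons = as.numeric(comparisons),
             window_shifts = as.numeric(shifts)),
        class = "search_stats"
      ),
      algorithm = algorithm,
      monotone = monotone
    ),
    class = "search_result"
  )
}

#' @export
print.search_stats <- function(x, ...) {
  cat(sprintf("char comparisons: %.0f, window shifts: %.0f\n",
              x$char_comparisons, x$window_shifts))
  invisible(x)
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("<%s> %d hit(s)\n", x$algorithm, nrow(x$hits)))
  if (nrow(x$hits) > 0) {
    shown <- utils::head(x$hits, 10)
    shown$mismatch_offsets <- vapply(
      shown$mismatch_offsets, paste, character(1), collapse = ","
    )
    print(shown, row.names = FALSE)
    if (nrow(x$hits) > 10) cat(sprintf("... and %d more\n", nrow(x$hits) - 10))
  }
  print(x$stats)
  invisible(x)
}

# internal: run code under a fixed seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}
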