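#' Read subject sequences
#'
#' Reads one or more sequences from FASTA (via Biostrings) or from a raw
#' text file (all whitespace stripped, single record named after the file).
#' Residues are case-folded to uppercase; record order is preserved and the
#' identifier is the first whitespace-delimited token of the header.
#'
#' @param path Readable file.
#' @param format `"fasta"` or `"raw"`.
#' @return List of [as_sequence()] objects.
#' @export
read_sequences <- function(path, format = c("fasta", "raw")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  if (format == "raw") {
    txt <- paste(gsub("\\s", "", readLines(path, warn = FALSE)),
                 collapse = "")
    if (nchar(txt) == 0L) stop(sprintf("empty sequence file: %s", path),
                               call. = FALSE)
    id <- tools::file_path_sans_ext(basename(path))
    return(list(as_sequence(txt, id)))
  }
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(trimws(lines) != "")
  if (length(nonblank) == 0L) {
    stop(sprintf("empty FASTA file: %s", path), call. = FALSE)
  }
  if (!startsWith(trimws(lines[nonblank[1L]]), ">")) {
    stop(sprintf("malformed FASTA in %s: sequence before header at line %d",
                 path, nonblank[1L]), call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  mapply(function(res, id) as_sequence(res, id),
         as.character(set), ids, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write sequences as FASTA
#'
#' @param seqs List of [as_sequence()] objects (or strings).
#' @param path Output file or open connection.
#' @param width Line width for wrapping residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (inherits(seqs, "opsi_sequence")) seqs <- list(seqs)
  if (inherits(path, "connection")) {
    con <- path
  } else {
    con <- file(path, "w")
    on.exit(close(con))
  }
  for (s in seqs) {
    s <- as_sequence(s)
    writeLines(paste0(">", s$id), con)
    if (s$length > 0) {
      starts <- seq(1L, s$length, by = width)
      writeLines(substring(s$residues, starts,
                           pmin(starts + width - 1L, s$length)), con)
    }
  }
  invisible(path)
}

#' Collect per-record hits into a flat table
#'
#' Runs one matcher over each record of a multi-record input independently
#' (hits never span records) and binds the results into one hit table.
#'
#' @param seqs List of sequences from [read_sequences()].
#' @param pat Pattern string or [pattern()] object.
#' @param method `"epm"`, `"naive"`, `"dfa"`, `"opsi"` or `"hamming"`.
#' @param max_mismatches Budget for the approximate methods.
#' @return Data frame with columns `record_id`, `start`, `end` (0-based
#'   half-open), `mismatch_count`, `mismatch_offsets` (comma-joined, empty
#'   for exact hits), plus attribute `stats` (summed over records).
#' @export
find_pattern <- function(seqs, pat,
                         method = c("epm", "naive", "dfa", "opsi", "hamming"),
                         max_mismatches = 0L) {
  method <- match.arg(method)
  pat <- pattern(pat)
  if (inherits(seqs, "opsi_sequence")) seqs <- list(seqs)
  dfa <- if (method == "dfa") build_dfa(pat) else NULL
  rows <- list()
  comparisons <- shifts <- 0
  for (s in seqs) {
    s <- as_sequence(s)
    res <- switch(method,
      epm = epm_search(s, pat),
      naive = naive_search(s, pat),
      dfa = dfa_search(s, dfa),
      opsi = opsi_search(s, pat, max_mismatches),
      hamming = hamming_window_search(s, pat, max_mismatches))
    comparisons <- comparisons + res$stats$char_comparisons
    shifts <- shifts + res$stats$window_shifts
    if (nrow(res$hits) > 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        record_id = s$id,
        start = res$hits$start,
        end = res$hits$end,
        mismatch_count = res$hits$mismatch_count,
        mismatch_offsets = vapply(res$hits$mismatch_offsets, paste,
                                  character(1), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(record_id = character(0), start = integer(0),
               end = integer(0), mismatch_count = integer(0),
               mismatch_offsets = character(0), stringsAsFactors = FALSE)
  attr(out, "stats") <- list(char_comparisons = comparisons,
                             window_shifts = shifts)
  out
}

#' Write hits as TSV or BED
#'
#' TSV carries a header line `record_id start end mismatches offsets`; BED
#' is 5-column (`chrom`, `chromStart`, `chromEnd`, `name = "."`,
#' `score = mismatch count`). All coordinates are 0-based half-open. Rows
#' are ordered by first appearance of the record, then by start.
#'
#' @param hits Data frame from [find_pattern()] (columns `record_id`,
#'   `start`, `end`, `mismatch_count`, `mismatch_offsets`).
#' @param path Output file or connection (`""` for stdout).
#' @param format `"tsv"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(hits),
            all(c("record_id", "start", "end", "mismatch_count")
                %in% names(hits)))
  ord <- order(match(hits$record_id, unique(hits$record_id)), hits$start)
  hits <- hits[ord, , drop = FALSE]
  if (format == "tsv") {
    out <- data.frame(record_id = hits$record_id, start = hits$start,
                      end = hits$end, mismatches = hits$mismatch_count,
                      offsets = if ("mismatch_offsets" %in% names(hits))
                        hits$mismatch_offsets else "",
                      stringsAsFactors = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE)
  } else {
    out <- data.frame(chrom = hits$record_id, chromStart = hits$start,
                      chromEnd = hits$end, name = ".",
                      score = hits$mismatch_count, stringsAsFactors = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' Read a TSV hit table written by [write_hits()]
#'
#' @param path TSV file with the `write_hits` header.
#' @return Data frame with the [find_pattern()] columns.
#' @export
read_hits <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(offsets = "character"))
  data.frame(record_id = as.character(out$record_id),
             start = as.integer(out$start), end = as.integer(out$end),
             mismatch_count = as.integer(out$mismatches),
             mismatch_offsets = out$offsets, stringsAsFactors = FALSE)
}
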