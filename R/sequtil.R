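#' Nucleotide sequence record
#'
#' Light container for a nucleotide sequence. Sequences are upper-cased on
#' construction and restricted to the alphabet `A`, `C`, `G`, `T`, `U`, `N`.
#' RNA input (containing `U`) is canonicalised to DNA space (`U` -> `T`) and
#' the original alphabet is recorded in the `is_rna` flag, so that seekRNA
#' sequences and DNA targets share one alphabet and complementarity is always
#' computed in DNA space.
#'
#' @param seq Single character string, length >= 1.
#' @param id Text label for the record.
#' @param is_rna Optional logical; if `NULL` it is inferred from the presence
#'   of `U` in the input.
#' @return An object of class `nucseq`: a list with elements `id`, `seq`
#'   (DNA-space string) and `is_rna`.
#' @examples
#' nucseq("acgu", id = "r1")   # canonicalised to ACGT, is_rna = TRUE
#' @export
nucseq <- function(seq, id = "seq", is_rna = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  s <- toupper(seq)
  if (nchar(s) < 1L) stop("sequence '", id, "' is empty")
  bad <- gregexpr("[^ACGTUN]", s)[[1L]]
  if (bad[1L] != -1L) {
    stop("invalid character '", substr(s, bad[1L], bad[1L]),
         "' in sequence '", id, "' at position ", bad[1L])
  }
  has_u <- grepl("U", s, fixed = TRUE)
  if (has_u && grepl("T", s, fixed = TRUE)) {
    stop("sequence '", id, "' mixes T and U")
  }
  if (is.null(is_rna)) is_rna <- has_u
  if (has_u) s <- chartr("U", "T", s)
  structure(list(id = id, seq = s, is_rna = is_rna), class = "nucseq")
}

#' @export
print.nucseq <- function(x, ...) {
  n <- nchar(x$seq)
  shown <- if (n > 60) paste0(substr(x$seq, 1, 57), "...") else x$seq
  cat(sprintf("<nucseq> %s (%d nt%s)\n  %s\n", x$id, n,
              if (isTRUE(x$is_rna)) ", RNA input" else "", shown))
  invisible(x)
}

#' @export
length.nucseq <- function(x) nchar(x$seq)

as_nucseq <- function(x, id = "seq") {
  if (inherits(x, "nucseq")) x else nucseq(x, id = id)
}

#' Reverse complement
#'
#' Watson-Crick reverse complement in DNA space; `N` maps to `N`. The record
#' id gains a `/rc` suffix.
#'
#' @param s A [nucseq] or a plain character string.
#' @return A `nucseq` (or plain string if the input was a plain string).
#' @examples
#' revcomp("GTGAAAATACTG")
#' @export
revcomp <- function(s) {
  if (is.character(s)) return(revcomp_str(toupper(s)))
  stopifnot(inherits(s, "nucseq"))
  structure(list(id = paste0(s$id, "/rc"), seq = revcomp_str(s$seq),
                 is_rna = s$is_rna), class = "nucseq")
}

revcomp_str <- function(s) {
  comp <- chartr("ACGTN", "TGCAN", s)
  vapply(comp, function(x) intToUtf8(rev(utf8ToInt(x))), "", USE.NAMES = FALSE)
}

seq_chars <- function(x) strsplit(if (inherits(x, "nucseq")) x$seq else x, "", fixed = TRUE)[[1L]]

#' Genomic interval (0-based, half-open)
#'
#' Internal coordinate convention for the whole package: 0-based, half-open,
#' so `end - start` is the length. Adapters to and from the 1-based inclusive
#' convention used by tabular homology hits and GenBank citations are lossless
#' round-trips.
#'
#' @param subject_id Reference sequence name.
#' @param start,end Integers, `0 <= start < end`.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `gint`.
#' @export
interval <- function(subject_id, start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(start) == 1L, length(end) == 1L, !is.na(start), !is.na(end))
  if (start < 0L) stop("interval start must be >= 0")
  if (end <= start) stop("interval end must be > start")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(subject_id = subject_id, start = start, end = end,
                 strand = strand), class = "gint")
}

#' @export
print.gint <- function(x, ...) {
  cat(sprintf("<gint> %s:[%d,%d) %s (%d nt)\n", x$subject_id, x$start, x$end,
              x$strand, iv_len(x)))
  invisible(x)
}

#' @rdname interval
#' @param x A `gint`.
#' @export
iv_len <- function(x) x$end - x$start

#' Convert 1-based inclusive coordinates to an internal interval
#'
#' `first > last` is interpreted as a minus-strand span (the tabular hit
#' convention, which has no strand column) and normalised.
#'
#' @param subject_id Reference name.
#' @param first,last 1-based inclusive endpoints.
#' @return A [interval()] object.
#' @export
iv_from_1based <- function(subject_id, first, last) {
  if (first <= last) interval(subject_id, first - 1L, last, "+")
  else interval(subject_id, last - 1L, first, "-")
}

#' @rdname iv_from_1based
#' @param x A `gint`.
#' @return For `iv_to_1based`, a named list `first`, `last` (swapped for minus
#'   strand, restoring the file convention).
#' @export
iv_to_1based <- function(x) {
  if (x$strand == "+") list(first = x$start + 1L, last = x$end)
  else list(first = x$end, last = x$start + 1L)
}

iv_overlaps <- function(a, b) {
  identical(a$subject_id, b$subject_id) && a$start < b$end && b$start < a$end
}

#' Read a FASTA file
#'
#' Multi-record FASTA, any wrap width. Records are validated and canonicalised
#' through [nucseq()]; duplicate ids and empty files are rejected.
#'
#' @param path File path.
#' @return Named list of [nucseq] records, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  recs <- mapply(function(s, id) nucseq(s, id = id),
                 as.character(set), ids, SIMPLIFY = FALSE)
  names(recs) <- ids
  recs
}

#' Write FASTA
#'
#' @param records List of [nucseq] (or a single one).
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (inherits(records, "nucseq")) records <- list(records)
  seqs <- vapply(records, function(r) r$seq, "")
  ids <- vapply(records, function(r) r$id, "")
  set <- Biostrings::BStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

#' Read BED-like intervals
#'
#' BED3/BED6, 0-based half-open, `#` comments and a `track` line ignored.
#'
#' @param path File path.
#' @return Data frame with columns `subject_id`, `start`, `end` and, when
#'   present, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)]
  if (!length(lines)) stop("empty BED file: ", path)
  df <- utils::read.table(text = lines, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED file needs at least 3 columns: ", path)
  names(df)[1:3] <- c("subject_id", "start", "end")
  if (ncol(df) >= 6L) names(df)[4:6] <- c("name", "score", "strand")
  if (any(df$end <= df$start)) stop("BED interval with end <= start in ", path)
  df
}

#' Write BED intervals
#'
#' @param df Data frame with `subject_id`, `start`, `end` (0-based half-open)
#'   and optionally `name`, `score`, `strand`.
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  cols <- intersect(c("subject_id", "start", "end", "name", "score", "strand"),
                    names(df))
  utils::write.table(df[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
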