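HIT_COLUMNS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
                 "qstart", "qend", "sstart", "send", "evalue", "bitscore",
                 "qcovs", "slen")
HIT_REQUIRED <- c("qseqid", "sseqid", "pident", "length", "evalue",
                  "sstart", "send", "slen", "qcovs")
HIT_NUMERIC <- c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
                 "sstart", "send", "evalue", "bitscore", "qcovs", "slen")

#' Read tabular homology hits
#'
#' Parses the standard 12-column tab-separated hit layout extended with
#' query-coverage-per-subject and subject-length columns
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore qcovs slen`). A header line is optional and `#`-prefixed
#' comment lines are ignored. Subject coordinates are 1-based inclusive;
#' `sstart > send` is the format's only minus-strand signal and is normalised
#' into a 0-based half-open interval with strand `"-"`. Row order is
#' preserved.
#'
#' @param path Tab-separated file path.
#' @return A data frame of class `hit_table` with the original columns plus
#'   `query_id`, `subject_id`, `qcov`, `subject_len`, `start`, `end`
#'   (0-based half-open) and `strand`.
#' @export
read_hits <- function(path) {
  if (!file.exists(path)) stop("hits file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("empty hits file: ", path)

  fields1 <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  has_header <- any(tolower(fields1) %in% HIT_COLUMNS) &&
    is.na(suppressWarnings(as.numeric(fields1[3L])))
  if (has_header) {
    cols <- tolower(fields1)
    lines <- lines[-1L]; lineno <- lineno[-1L]
    if (!length(lines)) stop("hits file has a header but no rows: ", path)
  } else {
    cols <- HIT_COLUMNS
  }
  missing_cols <- setdiff(HIT_REQUIRED, cols)
  if (length(missing_cols)) {
    stop("hits file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }

  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != length(cols))
  if (length(bad)) {
    stop("malformed hit row at line ", lineno[bad[1L]], ": expected ",
         length(cols), " fields, found ", nf[bad[1L]])
  }
  mat <- do.call(rbind, parts)
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- cols
  for (col in intersect(HIT_NUMERIC, cols)) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop("non-numeric value '", df[[col]][i], "' in column '", col,
           "' at line ", lineno[i])
    }
    df[[col]] <- v
  }
  normalize_hits(df)
}

# shared by read_hits() and the genome simulator so both emit identical tables
normalize_hits <- function(df) {
  df$query_id <- df$qseqid
  df$subject_id <- df$sseqid
  df$qcov <- df$qcovs
  df$subject_len <- df$slen
  minus <- df$sstart > df$send
  df$strand <- ifelse(minus, "-", "+")
  df$start <- as.integer(ifelse(minus, df$send, df$sstart)) - 1L
  df$end <- as.integer(ifelse(minus, df$sstart, df$send))
  class(df) <- c("hit_table", "data.frame")
  df
}

hit_interval <- function(hits, i) {
  interval(hits$subject_id[i], hits$start[i], hits$end[i], hits$strand[i])
}

#' Filter homology hits for target mining
#'
#' Applies the stringency filters used when collecting genomic IS copies:
#' minimum percent identity (95 or 100 are the two published tiers), full
#' query coverage, E-value at most `evalue_max`, and a subject-length window
#' that keeps assembled genomes while discarding small plasmid/partial
#' records.
#'
#' @param hits A `hit_table` from [read_hits()].
#' @param pident_min Minimum percent identity (default 95).
#' @param qcov_min Minimum query coverage per subject (default 100).
#' @param evalue_max Maximum E-value (default 0).
#' @param slen_min,slen_max Subject length window (defaults 1e5 and 1e7 bp).
#' @return Filtered `hit_table`; attribute `drop_counts` holds per-filter
#'   drop tallies.
#' @export
filter_hits <- function(hits, pident_min = 95, qcov_min = 100, evalue_max = 0,
                        slen_min = 1e5, slen_max = 1e7) {
  stopifnot(inherits(hits, "data.frame"))
  drops <- c(
    pident = sum(hits$pident < pident_min),
    qcov = sum(hits$qcov < qcov_min),
    evalue = sum(hits$evalue > evalue_max),
    slen = sum(hits$subject_len < slen_min | hits$subject_len > slen_max)
  )
  keep <- hits$pident >= pident_min & hits$qcov >= qcov_min &
    hits$evalue <= evalue_max &
    hits$subject_len >= slen_min & hits$subject_len <= slen_max
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hit_table", "data.frame")
  attr(out, "drop_counts") <- drops
  attr(out, "n_in") <- nrow(hits)
  out
}

#' Write a hit table back to the tabular format
#'
#' @param hits A `hit_table`.
#' @param path Output path.
#' @param header Write the column-name header line?
#' @export
write_hits <- function(hits, path, header = TRUE) {
  cols <- intersect(HIT_COLUMNS, names(hits))
  utils::write.table(hits[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}
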