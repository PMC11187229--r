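# All maximal approximate common substrings between character vectors a and b:
# windows along each diagonal with <= max_mm mismatches and length >= min_len
# that cannot be extended on either side. N never matches anything.
maximal_matches <- function(a, b, min_len, max_mm) {
  na <- length(a); nb <- length(b)
  out <- list()
  if (na < min_len || nb < min_len) return(out)
  for (d in seq.int(-(nb - min_len), na - min_len)) {
    # diagonal: a[i] vs b[i - d]
    i0 <- max(1L, d + 1L)
    i1 <- min(na, nb + d)
    len <- i1 - i0 + 1L
    if (len < min_len) next
    av <- a[i0:i1]; bv <- b[(i0 - d):(i1 - d)]
    mism <- (av != bv) | av == "N" | bv == "N"
    cum <- c(0L, cumsum(mism))
    # two-pointer: reach[s] = furthest end with <= max_mm mismatches
    reach <- integer(len)
    e <- 0L
    for (s in seq_len(len)) {
      if (e < s) e <- s - 1L
      while (e < len && cum[e + 2L] - cum[s] <= max_mm) e <- e + 1L
      reach[s] <- e
    }
    for (s in seq_len(len)) {
      e <- reach[s]
      if (e - s + 1L < min_len) next
      if (s > 1L && reach[s - 1L] >= e) next    # left-extendable
      out[[length(out) + 1L]] <- list(
        a_start = i0 + s - 2L,                  # 0-based on a
        b_start = i0 - d + s - 2L,              # 0-based on b
        length = e - s + 1L,
        mismatches = cum[e + 1L] - cum[s - 1L + 1L])
    }
  }
  out
}

#' Scan a seekRNA for target-complementary segments
#'
#' Enumerates all maximal segments of the seekRNA of length >=
#' `min_match_len` that base-pair (antiparallel Watson-Crick, up to
#' `max_mismatch` mismatches, no G:U wobble -- the seekRNA pairs with DNA)
#' with the top (T) or bottom (B) strand of the target. The best match per
#' strand is the longest, ties broken by fewest mismatches then the 5'-most
#' position on the seekRNA. The 5'->3' order of the two best matches on the
#' seekRNA is the family diagnostic: the top-strand match precedes the
#' bottom-strand match in IS1111-family seekRNAs and the order is reversed
#' in the IS110 family.
#'
#' @param seekrna A [nucseq] (RNA accepted; matching is in DNA space).
#' @param target A [nucseq]: the target's top strand, 5'->3'.
#' @param min_match_len Minimum reported segment length (default 7; short
#'   enough for figure-scale matches, long enough to suppress random 4-mer
#'   noise on ~80-nt RNAs).
#' @param max_mismatch Allowed mismatches per segment (default 0).
#' @param insertion_point Optional 0-based index on the target top strand;
#'   if given, the report notes whether the combined match footprint
#'   straddles it.
#' @return Object of class `scan_report`: `t_matches`/`b_matches` (data
#'   frames: `rna_start`, `rna_end`, `target_start`, `target_end` in top
#'   strand coordinates, `length`, `mismatches`), `best_t`, `best_b`,
#'   `order` (`"T-before-B"`, `"B-before-T"`, `"undetermined"`),
#'   `overlap_in_target`, `insertion_point_covered`.
#' @export
scan_seekrna <- function(seekrna, target, min_match_len = 7L,
                         max_mismatch = 0L, insertion_point = NULL) {
  seekrna <- as_nucseq(seekrna, id = "seekrna")
  target <- as_nucseq(target, id = "target")
  if (nchar(seekrna$seq) < min_match_len) {
    stop("seekRNA shorter than min_match_len")
  }
  s <- seq_chars(seekrna)
  ttop <- seq_chars(target)
  tbot <- seq_chars(revcomp(target))
  nt <- length(ttop)
  # an RNA segment pairs antiparallel with a top-strand window iff it equals
  # (in DNA space) a substring of the bottom strand, and vice versa
  t_raw <- maximal_matches(s, tbot, min_match_len, max_mismatch)
  b_raw <- maximal_matches(s, ttop, min_match_len, max_mismatch)
  as_df <- function(raw, top_coords) {
    if (!length(raw)) {
      return(data.frame(rna_start = integer(), rna_end = integer(),
                        target_start = integer(), target_end = integer(),
                        length = integer(), mismatches = integer()))
    }
    df <- do.call(rbind, lapply(raw, function(m) {
      ts <- if (top_coords) m$b_start else nt - m$b_start - m$length
      data.frame(rna_start = m$a_start, rna_end = m$a_start + m$length,
                 target_start = ts, target_end = ts + m$length,
                 length = m$length, mismatches = m$mismatches)
    }))
    df[order(df$rna_start, df$target_start), , drop = FALSE]
  }
  t_df <- as_df(t_raw, top_coords = FALSE)
  b_df <- as_df(b_raw, top_coords = TRUE)
  pick_best <- function(df) {
    if (!nrow(df)) return(NULL)
    df[order(-df$length, df$mismatches, df$rna_start)[1L], , drop = FALSE]
  }
  best_t <- pick_best(t_df)
  best_b <- pick_best(b_df)
  ord <- if (is.null(best_t) || is.null(best_b)) "undetermined"
  else if (best_t$rna_start < best_b$rna_start) "T-before-B"
  else if (best_t$rna_start > best_b$rna_start) "B-before-T"
  else "undetermined"
  overlap <- !is.null(best_t) && !is.null(best_b) &&
    best_t$target_start < best_b$target_end &&
    best_b$target_start < best_t$target_end
  ip_cov <- NA
  if (!is.null(insertion_point) && !is.null(best_t) && !is.null(best_b)) {
    lo <- min(best_t$target_start, best_b$target_start)
    hi <- max(best_t$target_end, best_b$target_end)
    ip_cov <- lo < insertion_point && insertion_point < hi
  }
  structure(list(
    seekrna_id = seekrna$id, target_id = target$id,
    t_matches = t_df, b_matches = b_df, best_t = best_t, best_b = best_b,
    order = ord, overlap_in_target = overlap,
    insertion_point = insertion_point, insertion_point_covered = ip_cov,
    min_match_len = min_match_len, max_mismatch = max_mismatch),
    class = "scan_report")
}

#' @export
print.scan_report <- function(x, ...) {
  cat(sprintf("<scan_report> %s vs %s\n", x$seekrna_id, x$target_id))
  cat(sprintf("  T matches: %d, B matches: %d\n",
              nrow(x$t_matches), nrow(x$b_matches)))
  for (side in c("best_t", "best_b")) {
    m <- x[[side]]
    if (!is.null(m)) {
      cat(sprintf("  %s: rna [%d,%d), target [%d,%d), %d nt, %d mm\n",
                  toupper(substr(side, 6, 6)), m$rna_start, m$rna_end,
                  m$target_start, m$target_end, m$length, m$mismatches))
    }
  }
  cat("  order:", x$order,
      if (isTRUE(x$overlap_in_target)) "(matches overlap in target)" else "",
      "\n")
  if (!is.na(x$insertion_point_covered) && length(x$insertion_point_covered)) {
    cat("  insertion point straddled:", x$insertion_point_covered, "\n")
  }
  invisible(x)
}

#' Classify the family from the seekRNA match order
#'
#' Top-strand match 5' of the bottom-strand match is the IS1111 pattern; the
#' reversed order is the IS110 pattern.
#'
#' @param report A `scan_report` (or an order string).
#' @return `"IS1111-pattern"`, `"IS110-pattern"` or `"undetermined"`.
#' @export
classify_family_by_order <- function(report) {
  ord <- if (inherits(report, "scan_report")) report$order else report
  switch(ord,
         "T-before-B" = "IS1111-pattern",
         "B-before-T" = "IS110-pattern",
         "undetermined")
}

#' Call the peak seekRNA from read coverage
#'
#' Computes per-base coverage from read intervals mapped to one reference
#' (the IS or its NCR) and calls the primary peak as the maximal-length
#' contiguous run with coverage >= `alpha * max`, plus the maximal run at a
#' lower threshold as the "long form" candidate (the precursor-like RNA that
#' fully includes the peak seekRNA). Output is invariant to interval order.
#'
#' @param intervals Data frame with `start`, `end` (0-based half-open), e.g.
#'   from [read_bed()], or a list of [interval()] objects.
#' @param ref_len Reference length; inferred from the intervals if `NULL`.
#' @param alpha Primary threshold as a fraction of the coverage maximum
#'   (default 0.5).
#' @param long_alpha Long-form threshold (default 0.1).
#' @param orf_end Optional 0-based coordinate of the transposase stop (or
#'   start) used to report peak positions relative to the ORF boundary.
#' @return Object of class `peak_call`: `coverage`, `max_coverage`, `peak`
#'   (interval), `peak_len`, `long` (interval), `long_len`, `peak_rel`,
#'   `long_rel` (offsets from `orf_end`, when supplied).
#' @export
call_peak <- function(intervals, ref_len = NULL, alpha = 0.5,
                      long_alpha = 0.1, orf_end = NULL) {
  if (is.list(intervals) && !is.data.frame(intervals) &&
      length(intervals) && inherits(intervals[[1L]], "gint")) {
    intervals <- data.frame(
      start = vapply(intervals, `[[`, 0L, "start"),
      end = vapply(intervals, `[[`, 0L, "end"))
  }
  if (!nrow(intervals)) stop("no read intervals supplied")
  stopifnot(alpha > 0, alpha <= 1, long_alpha > 0, long_alpha <= 1)
  if (is.null(ref_len)) ref_len <- max(intervals$end)
  if (any(intervals$start < 0) || any(intervals$end > ref_len)) {
    stop("read interval outside [0, ref_len)")
  }
  cov <- integer(ref_len)
  delta <- integer(ref_len + 1L)
  for (i in seq_len(nrow(intervals))) {
    delta[intervals$start[i] + 1L] <- delta[intervals$start[i] + 1L] + 1L
    delta[intervals$end[i] + 1L] <- delta[intervals$end[i] + 1L] - 1L
  }
  cov <- cumsum(delta[seq_len(ref_len)])
  maxc <- max(cov)
  longest_run <- function(thresh) {
    r <- rle(cov >= thresh)
    if (!any(r$values)) return(NULL)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])]
    interval("coverage", starts[best] - 1L, ends[best])
  }
  peak <- longest_run(alpha * maxc)
  long <- longest_run(long_alpha * maxc)
  rel <- function(iv) {
    if (is.null(iv) || is.null(orf_end)) return(NULL)
    c(start = iv$start - orf_end, end = iv$end - orf_end)
  }
  structure(list(coverage = cov, max_coverage = maxc,
                 peak = peak, peak_len = if (is.null(peak)) 0L else iv_len(peak),
                 long = long, long_len = if (is.null(long)) 0L else iv_len(long),
                 peak_rel = rel(peak), long_rel = rel(long),
                 alpha = alpha, long_alpha = long_alpha, orf_end = orf_end),
            class = "peak_call")
}

#' @export
print.peak_call <- function(x, ...) {
  cat(sprintf("<peak_call> max coverage %d\n", x$max_coverage))
  if (!is.null(x$peak)) {
    cat(sprintf("  peak (>= %.2f*max): [%d,%d), %d nt\n", x$alpha,
                x$peak$start, x$peak$end, x$peak_len))
  }
  if (!is.null(x$long)) {
    cat(sprintf("  long form (>= %.2f*max): [%d,%d), %d nt\n", x$long_alpha,
                x$long$start, x$long$end, x$long_len))
  }
  if (!is.null(x$peak_rel)) {
    cat(sprintf("  peak relative to ORF boundary: %+d..%+d\n",
                x$peak_rel["start"], x$peak_rel["end"]))
  }
  invisible(x)
}
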