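#' Design a reprogrammed seekRNA and donor flanks for a new target
#'
#' Replicates the published reprogramming logic in silico: the best top- and
#' bottom-strand matches of the original seekRNA against its natural target
#' are located, their target windows are mapped onto the new target at the
#' same offsets relative to the insertion point, and the corresponding
#' antiparallel complements are written into the seekRNA at the original
#' positions. All other seekRNA bases (stem/scaffold) are untouched and the
#' design is substitution-only: the seekRNA length never changes. The donor
#' left/right flanks (LF/RF) are the new target split at its insertion
#' point. The plan embeds a validation scan of the new seekRNA against the
#' new target.
#'
#' The designer never flips the target: insertion is orientation-specific,
#' so choosing the strand of the new target is the caller's responsibility.
#'
#' @param seekrna,target [nucseq]: the original seekRNA and target top
#'   strand.
#' @param insertion_point 0-based insertion point on the original target.
#' @param new_target [nucseq]: new target top strand.
#' @param new_insertion_point 0-based insertion point on the new target.
#' @param min_match_len,max_mismatch Scanner settings ([scan_seekrna()]).
#' @param lf_len,rf_len Optional donor flank lengths; by default the whole
#'   new target is split.
#' @return Object of class `reprogram_plan`: `original` (scan report),
#'   `new_seekrna`, `new_left_flank`, `new_right_flank`, `edits` (data frame
#'   of 0-based rna position, old, new), `validation` (scan report),
#'   `validation_ok`.
#' @export
design_reprogram <- function(seekrna, target, insertion_point, new_target,
                             new_insertion_point, min_match_len = 7L,
                             max_mismatch = 0L, lf_len = NULL, rf_len = NULL) {
  seekrna <- as_nucseq(seekrna, id = "seekrna")
  target <- as_nucseq(target, id = "target")
  new_target <- as_nucseq(new_target, id = "new_target")
  rep0 <- scan_seekrna(seekrna, target, min_match_len = min_match_len,
                       max_mismatch = max_mismatch,
                       insertion_point = insertion_point)
  if (is.null(rep0$best_t) || is.null(rep0$best_b)) {
    stop("original seekRNA/target pair lacks a match on one strand; ",
         "cannot anchor the design")
  }
  nn <- nchar(new_target$seq)
  map_window <- function(m) {
    c(start = m$target_start - insertion_point + new_insertion_point,
      end = m$target_end - insertion_point + new_insertion_point)
  }
  tw <- map_window(rep0$best_t)
  bw <- map_window(rep0$best_b)
  if (any(c(tw, bw) < 0) || any(c(tw["end"], bw["end"]) > nn)) {
    stop("target too short for match footprint")
  }
  new_top <- new_target$seq
  t_repl <- revcomp_str(substr(new_top, tw["start"] + 1L, tw["end"]))
  b_repl <- substr(new_top, bw["start"] + 1L, bw["end"])
  chars <- seq_chars(seekrna)
  new_chars <- chars
  write_span <- function(nc, span_start, repl) {
    rc <- strsplit(repl, "")[[1L]]
    idx <- span_start + seq_along(rc)          # 1-based positions
    conflict <- idx[nc[idx] != chars[idx] & nc[idx] != rc]
    if (length(conflict)) {
      stop("inconsistent overlap edit at seekRNA position ", conflict[1L] - 1L)
    }
    nc[idx] <- rc
    nc
  }
  new_chars <- write_span(new_chars, rep0$best_t$rna_start, t_repl)
  new_chars <- write_span(new_chars, rep0$best_b$rna_start, b_repl)
  changed <- which(new_chars != chars)
  edits <- data.frame(position = changed - 1L, old = chars[changed],
                      new = new_chars[changed], stringsAsFactors = FALSE)
  new_seekrna <- nucseq(paste(new_chars, collapse = ""),
                        id = paste0(seekrna$id, "/reprogrammed"),
                        is_rna = seekrna$is_rna)
  lf <- substr(new_top, 1L, new_insertion_point)
  rf <- substr(new_top, new_insertion_point + 1L, nn)
  if (!is.null(lf_len) && nchar(lf) > lf_len) {
    lf <- substr(lf, nchar(lf) - lf_len + 1L, nchar(lf))
  }
  if (!is.null(rf_len) && nchar(rf) > rf_len) rf <- substr(rf, 1L, rf_len)
  validation <- scan_seekrna(new_seekrna, new_target,
                             min_match_len = min_match_len,
                             max_mismatch = max_mismatch,
                             insertion_point = new_insertion_point)
  ok <- identical(validation$order, rep0$order) &&
    !is.null(validation$best_t) && !is.null(validation$best_b) &&
    validation$best_t$length == rep0$best_t$length &&
    validation$best_b$length == rep0$best_b$length
  structure(list(
    original = rep0, target = target, insertion_point = insertion_point,
    new_target = new_target, new_insertion_point = new_insertion_point,
    new_seekrna = new_seekrna,
    new_left_flank = if (nchar(lf)) nucseq(lf, id = "LF") else NULL,
    new_right_flank = if (nchar(rf)) nucseq(rf, id = "RF") else NULL,
    edits = edits, validation = validation, validation_ok = ok),
    class = "reprogram_plan")
}

#' @export
print.reprogram_plan <- function(x, ...) {
  cat("<reprogram_plan>\n")
  cat(sprintf("  %d edit(s) in a %d-nt seekRNA; order %s -> %s\n",
              nrow(x$edits), nchar(x$new_seekrna$seq),
              x$original$order, x$validation$order))
  cat(sprintf("  LF %d nt | RF %d nt (new target %d nt, insertion point %d)\n",
              if (is.null(x$new_left_flank)) 0L else nchar(x$new_left_flank$seq),
              if (is.null(x$new_right_flank)) 0L else nchar(x$new_right_flank$seq),
              nchar(x$new_target$seq), x$new_insertion_point))
  cat("  validation:", if (x$validation_ok) "order and match lengths preserved"
      else "MISMATCH with original scan", "\n")
  invisible(x)
}

#' Lay out a donor mini-IS construct
#'
#' Emits the ordered donor annotation LF-LE-cargo-RE-RF, where LF/RF carry
#' the new target split at the insertion point and LE/RE are the outer IS
#' ends taken from the element when one is supplied. Also emits the
#' predicted minicircle junction (RE abutted to LE, the configuration that
#' creates the junction promoter) and the reconstituted target for
#' verification primers.
#'
#' @param new_target A [nucseq]: target top strand.
#' @param insertion_point 0-based split point, `0..len`; 0 or `len` is
#'   flagged degenerate (one empty flank).
#' @param le_len,re_len IS end lengths in bp (published mini-IS examples:
#'   LE 50/RE 46 for an IS1111-family donor, LE 29/RE 16 for an IS110-family
#'   donor).
#' @param cargo_id Label for the cargo segment.
#' @param element Optional [nucseq] of the IS; its first `le_len` and last
#'   `re_len` nt become LE/RE and the remainder is replaced by the cargo.
#' @param cargo_len Cargo length when no element is supplied (default 0).
#' @return Object of class `donor_layout`: `features` (data frame with
#'   0-based donor coordinates and sequences), `minicircle_junction`,
#'   `reconstituted_target`, `degenerate`.
#' @export
build_donor_layout <- function(new_target, insertion_point, le_len, re_len,
                               cargo_id = "cargo", element = NULL,
                               cargo_len = NULL) {
  new_target <- as_nucseq(new_target, id = "new_target")
  n <- nchar(new_target$seq)
  ip <- as.integer(insertion_point)
  if (ip < 0L || ip > n) stop("insertion point outside new_target")
  stopifnot(le_len > 0L, re_len > 0L)
  lf <- substr(new_target$seq, 1L, ip)
  rf <- substr(new_target$seq, ip + 1L, n)
  if (!is.null(element)) {
    element <- as_nucseq(element, id = "element")
    ne <- nchar(element$seq)
    if (ne < le_len + re_len) stop("element shorter than LE + RE")
    le <- substr(element$seq, 1L, le_len)
    re <- substr(element$seq, ne - re_len + 1L, ne)
    if (is.null(cargo_len)) cargo_len <- ne - le_len - re_len
  } else {
    le <- strrep("N", le_len)
    re <- strrep("N", re_len)
    if (is.null(cargo_len)) cargo_len <- 0L
  }
  cargo <- strrep("N", cargo_len)
  segs <- list(LF = lf, LE = le, cargo = cargo, RE = re, RF = rf)
  names(segs)[3L] <- cargo_id
  lens <- vapply(segs, nchar, 0L)
  ends <- cumsum(lens)
  feats <- data.frame(feature = names(segs), start = ends - lens, end = ends,
                      length = lens, seq = unlist(segs, use.names = FALSE),
                      stringsAsFactors = FALSE)
  feats <- feats[feats$length > 0L, , drop = FALSE]
  rownames(feats) <- NULL
  structure(list(
    features = feats,
    minicircle_junction = paste0(re, le),
    reconstituted_target = paste0(lf, rf),
    degenerate = ip == 0L || ip == n), class = "donor_layout")
}

#' @export
print.donor_layout <- function(x, ...) {
  cat("<donor_layout>", paste(x$features$feature, collapse = "-"), "\n")
  for (i in seq_len(nrow(x$features))) {
    cat(sprintf("  %-8s [%d,%d) %d nt\n", x$features$feature[i],
                x$features$start[i], x$features$end[i], x$features$length[i]))
  }
  if (x$degenerate) cat("  warning: degenerate split (one empty flank)\n")
  invisible(x)
}
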