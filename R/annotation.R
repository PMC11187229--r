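ORF_STARTS <- c("ATG", "GTG", "TTG")
ORF_STOPS <- c("TAA", "TAG", "TGA")

# all stop-terminated ORFs >= min_aa codons in the three frames of one strand;
# coordinates are 0-based half-open on that strand, spans include the stop codon
orfs_one_strand <- function(chars, min_aa) {
  n <- length(chars)
  out <- list()
  for (f in 0:2) {
    starts <- seq.int(f + 1L, n - 2L, by = 3L)
    if (length(starts) < 2L) next
    codons <- paste0(chars[starts], chars[starts + 1L], chars[starts + 2L])
    stop_i <- which(codons %in% ORF_STOPS)
    start_i <- which(codons %in% ORF_STARTS)
    prev <- 0L
    for (si in stop_i) {
      cand <- start_i[start_i > prev & start_i < si]
      if (length(cand)) {
        a <- cand[1L]
        aa <- si - a                       # codons before the stop
        if (aa >= min_aa) {
          out[[length(out) + 1L]] <-
            list(start = starts[a] - 1L, end = starts[si] + 2L, aa = aa)
        }
      }
      prev <- si
    }
  }
  out
}

#' Find the transposase open reading frame
#'
#' Scans both strands and all three frames for the longest stop-terminated
#' open reading frame of at least `min_aa` codons, using the bacterial start
#' codons `ATG`, `GTG`, `TTG`. IS110/IS1111-family transposases run roughly
#' 315-450 aa, so the default floor of 250 aa excludes spurious short frames
#' while keeping every plausible DEDD transposase. Ties on length are broken
#' in favour of the plus strand, then the 5'-most start.
#'
#' @param element A [nucseq].
#' @param min_aa Minimum ORF length in amino acids (stop codon excluded).
#' @return A [interval()] on the element (strand = ORF strand). If equally
#'   long ORFs overlap on opposite strands, attribute `ambiguous` carries a
#'   warning note.
#' @export
find_tnp_orf <- function(element, min_aa = 250L) {
  element <- as_nucseq(element)
  n <- nchar(element$seq)
  if (n < 3L * min_aa) stop("element shorter than 3*min_aa")
  fwd <- orfs_one_strand(seq_chars(element), min_aa)
  rev <- orfs_one_strand(seq_chars(revcomp(element)), min_aa)
  cand <- c(
    lapply(fwd, function(o) c(o, list(strand = "+"))),
    lapply(rev, function(o) list(start = n - o$end, end = n - o$start,
                                 aa = o$aa, strand = "-"))
  )
  if (!length(cand)) stop("no transposase ORF of >= ", min_aa, " aa found")
  lens <- vapply(cand, function(o) o$end - o$start, 0L)
  plus <- vapply(cand, function(o) o$strand == "+", TRUE)
  starts <- vapply(cand, function(o) o$start, 0L)
  ord <- order(-lens, !plus, starts)
  best <- cand[[ord[1L]]]
  res <- interval(element$id, best$start, best$end, best$strand)
  top <- which(lens == max(lens))
  if (length(top) > 1L) {
    others <- setdiff(top, ord[1L])
    clash <- any(vapply(others, function(i) {
      cand[[i]]$strand != best$strand &&
        cand[[i]]$start < best$end && best$start < cand[[i]]$end
    }, TRUE))
    if (clash) {
      attr(res, "ambiguous") <-
        "equally long overlapping ORFs on both strands"
    }
  }
  res
}

#' Classify the non-coding region location
#'
#' An NCR is called "long" when it is at least `long_threshold` nt (default
#' 100 nt; the literature speaks of an NCR "of significant length" without
#' quantifying it). Lengths are measured in the ORF's reading orientation:
#' upstream = element 5' end to ORF start, downstream = ORF stop to element
#' 3' end.
#'
#' @param upstream_len,downstream_len NCR lengths in nt (ORF orientation).
#' @param long_threshold Minimum length for a "long" NCR.
#' @return One of `"downstream"`, `"upstream"`, `"both"`, `"none"`.
#' @export
classify_ncr <- function(upstream_len, downstream_len, long_threshold = 100L) {
  stopifnot(upstream_len >= 0, downstream_len >= 0)
  up <- upstream_len >= long_threshold
  down <- downstream_len >= long_threshold
  if (up && down) "both" else if (up) "upstream" else if (down) "downstream" else "none"
}

#' Find sub-terminal inverted repeats (sTIR)
#'
#' IS1111-family elements carry inverted repeats, usually 11-13 bp with a
#' perfect or near-perfect match, set in from the ends by short terminal
#' extensions (7 bp on the left and 3 bp on the right, occasionally 6/3).
#' The search window of width `window` starts immediately after the left
#' extension and ends immediately before the right extension; the longest
#' segment pair with `left == revcomp(right)` up to `max_mismatch` mismatches
#' and length >= `min_ir_len` is returned. A repeat must begin and end with a
#' paired base (terminal mismatches are trimmed, they are not part of the
#' repeat), so a perfectly planted repeat is reported at its exact length
#' with 0 mismatches even when `max_mismatch > 0`. Absence is a valid
#' result.
#'
#' Ties on length are broken by fewest mismatches, then by the pair closest
#' to the termini (a mirror-symmetric criterion, so the finder and its
#' reverse-complement report the same repeat).
#'
#' @param element A [nucseq].
#' @param min_ir_len Minimum repeat length (default 11).
#' @param max_mismatch Maximum mismatches between left and revcomp(right)
#'   (default 1).
#' @param left_ext,right_ext Terminal extension lengths (defaults 7 and 3).
#' @param window Search window width per side (default 30).
#' @return `NULL`, or a list of class `stir` with `left`/`right` intervals,
#'   `length` and `mismatches`.
#' @export
find_stir <- function(element, min_ir_len = 11L, max_mismatch = 1L,
                      left_ext = 7L, right_ext = 3L, window = 30L) {
  element <- as_nucseq(element)
  n <- nchar(element$seq)
  if (n <= left_ext + right_ext + 2L * min_ir_len) {
    stop("element too short for sTIR search")
  }
  window <- min(window, (n - left_ext - right_ext) %/% 2L)
  chars <- seq_chars(element)
  lreg <- chars[(left_ext + 1L):(left_ext + window)]
  r0 <- n - right_ext - window              # 0-based start of right region
  rreg <- chars[(r0 + 1L):(n - right_ext)]
  best <- NULL
  for (L in seq.int(window, min_ir_len)) {
    cands <- list()
    for (i in 0:(window - L)) {
      lseg <- lreg[(i + 1L):(i + L)]
      lcomp <- rev(chartr("ACGTN", "TGCAN", lseg))   # revcomp in char space
      for (j in 0:(window - L)) {
        rseg <- rreg[(j + 1L):(j + L)]
        pairs <- lcomp == rseg & rseg != "N"
        mm <- sum(!pairs)
        if (mm <= max_mismatch && pairs[1L] && pairs[L]) {
          cands[[length(cands) + 1L]] <-
            list(i = i, j = j, mm = mm, outer = i + (window - j - L))
        }
      }
    }
    if (length(cands)) {
      mms <- vapply(cands, `[[`, 0, "mm")
      outers <- vapply(cands, `[[`, 0, "outer")
      is <- vapply(cands, `[[`, 0, "i")
      pick <- cands[[order(mms, outers, is)[1L]]]
      best <- structure(list(
        left = interval(element$id, left_ext + pick$i, left_ext + pick$i + L),
        right = interval(element$id, r0 + pick$j, r0 + pick$j + L),
        length = L, mismatches = pick$mm), class = "stir")
      break
    }
  }
  best
}

#' @export
print.stir <- function(x, ...) {
  cat(sprintf("<stir> %d bp, %d mismatch(es): left [%d,%d), right [%d,%d)\n",
              x$length, x$mismatches, x$left$start, x$left$end,
              x$right$start, x$right$end))
  invisible(x)
}

#' Call the IS family from sTIR and NCR evidence
#'
#' IS1111-like requires an sTIR plus a long NCR downstream of the transposase
#' (or on both sides); IS110-like requires absence of an sTIR plus an
#' upstream (or both-sides) long NCR. Conflicting evidence yields
#' `"ambiguous"` with the conflict noted; an sTIR together with an upstream
#' NCR is the known ISMtsp17-like exception.
#'
#' @param ncr_class Output of [classify_ncr()].
#' @param stir_present Logical, or the result of [find_stir()].
#' @return List with `call` (`"IS1111-like"`, `"IS110-like"` or
#'   `"ambiguous"`) and `notes` (character vector of conflicts).
#' @export
call_family <- function(ncr_class, stir_present) {
  if (!is.logical(stir_present)) stir_present <- !is.null(stir_present)
  stopifnot(ncr_class %in% c("downstream", "upstream", "both", "none"))
  notes <- character()
  if (stir_present && ncr_class %in% c("downstream", "both")) {
    call <- "IS1111-like"
  } else if (!stir_present && ncr_class %in% c("upstream", "both")) {
    call <- "IS110-like"
  } else {
    call <- "ambiguous"
    if (stir_present && ncr_class == "upstream") {
      notes <- c(notes, "sTIR present but NCR upstream: ISMtsp17-like exception")
    } else if (stir_present) {
      notes <- c(notes, paste0("sTIR present but NCR class '", ncr_class, "'"))
    } else {
      notes <- c(notes, paste0("no sTIR but NCR class '", ncr_class, "'"))
    }
  }
  list(call = call, notes = notes)
}

#' Annotate an IS element
#'
#' Runs the full per-element annotation: transposase ORF ([find_tnp_orf()]),
#' NCR lengths and class ([classify_ncr()]), sub-terminal inverted repeats
#' ([find_stir()]) and the family call ([call_family()]). Elements are
#' assumed deposited with their left end 5'; set `flip = TRUE` to reverse
#' the orientation first.
#'
#' @param element A [nucseq].
#' @param min_aa,long_ncr,ir_min,ir_mismatch,ext_left,ext_right,ir_window
#'   Tuning parameters passed through to the component finders.
#' @param flip Reverse-complement the element before annotating.
#' @return An object of class `is_annotation`.
#' @export
annotate_element <- function(element, min_aa = 250L, long_ncr = 100L,
                             ir_min = 11L, ir_mismatch = 1L,
                             ext_left = 7L, ext_right = 3L, ir_window = 30L,
                             flip = FALSE) {
  element <- as_nucseq(element)
  if (flip) element <- revcomp(element)
  n <- nchar(element$seq)
  orf <- find_tnp_orf(element, min_aa = min_aa)
  if (orf$strand == "+") {
    up <- orf$start
    down <- n - orf$end
  } else {
    up <- n - orf$end
    down <- orf$start
  }
  ncr_class <- classify_ncr(up, down, long_threshold = long_ncr)
  stir <- find_stir(element, min_ir_len = ir_min, max_mismatch = ir_mismatch,
                    left_ext = ext_left, right_ext = ext_right,
                    window = ir_window)
  fam <- call_family(ncr_class, stir)
  notes <- fam$notes
  if (!is.null(attr(orf, "ambiguous"))) notes <- c(notes, attr(orf, "ambiguous"))
  structure(list(
    element = element, tnp_orf = orf,
    upstream_ncr_len = up, downstream_ncr_len = down, ncr_class = ncr_class,
    stir = stir, left_ext_len = ext_left, right_ext_len = ext_right,
    family_call = fam$call, notes = notes), class = "is_annotation")
}

#' @export
print.is_annotation <- function(x, ...) {
  cat(sprintf("<is_annotation> %s (%d nt)\n", x$element$id, nchar(x$element$seq)))
  cat(sprintf("  tnp ORF: [%d,%d) strand %s (%d aa)\n", x$tnp_orf$start,
              x$tnp_orf$end, x$tnp_orf$strand, iv_len(x$tnp_orf) %/% 3L - 1L))
  cat(sprintf("  NCR: upstream %d nt, downstream %d nt -> %s\n",
              x$upstream_ncr_len, x$downstream_ncr_len, x$ncr_class))
  if (is.null(x$stir)) cat("  sTIR: absent\n")
  else cat(sprintf("  sTIR: %d bp, %d mismatch(es)\n", x$stir$length,
                   x$stir$mismatches))
  cat("  family:", x$family_call, "\n")
  for (nt in x$notes) cat("  note:", nt, "\n")
  invisible(x)
}

#' Tabulate annotations
#'
#' @param anns List of `is_annotation` objects (or a single one).
#' @return One row per element: ORF coordinates/strand, NCR lengths and
#'   class, sTIR coordinates, family call.
#' @export
annotation_table <- function(anns) {
  if (inherits(anns, "is_annotation")) anns <- list(anns)
  do.call(rbind, lapply(anns, function(a) {
    data.frame(
      id = a$element$id, length = nchar(a$element$seq),
      orf_start = a$tnp_orf$start, orf_end = a$tnp_orf$end,
      orf_strand = a$tnp_orf$strand,
      upstream_ncr = a$upstream_ncr_len, downstream_ncr = a$downstream_ncr_len,
      ncr_class = a$ncr_class,
      stir_len = if (is.null(a$stir)) NA_integer_ else a$stir$length,
      stir_mismatches = if (is.null(a$stir)) NA_integer_ else a$stir$mismatches,
      stir_left = if (is.null(a$stir)) NA_integer_ else a$stir$left$start,
      stir_right = if (is.null(a$stir)) NA_integer_ else a$stir$right$start,
      family = a$family_call,
      notes = paste(a$notes, collapse = "; "),
      stringsAsFactors = FALSE)
  }))
}
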