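#' Extract pre-insertion flanks around IS hits
#'
#' For every hit, takes the `flank_len` nt immediately 5' and 3' of the hit
#' interval on the subject. Minus-strand hits are reverse-complemented and
#' the two flanks swapped, so `left`/`right` are always in the IS's own
#' orientation. Hits closer than `flank_len` to a contig edge are skipped
#' with a recorded reason (padding would distort downstream column counts).
#'
#' @param hits A `hit_table` ([read_hits()]).
#' @param subjects Named list of [nucseq] (e.g. from [read_fasta()]).
#' @param flank_len Flank length in nt (default 200).
#' @return List with `pairs` (list of `flank_pair`: `hit` row index, `hit_iv`,
#'   `left`, `right`) and `skipped` (data frame of row/reason).
#' @export
extract_flanks <- function(hits, subjects, flank_len = 200L) {
  stopifnot(inherits(hits, "data.frame"))
  flank_len <- as.integer(flank_len)
  missing_ids <- setdiff(unique(hits$subject_id), names(subjects))
  if (length(missing_ids)) {
    stop("subject sequence(s) missing: ", paste(missing_ids, collapse = ", "))
  }
  pairs <- list()
  skipped <- list()
  for (i in seq_len(nrow(hits))) {
    subj <- subjects[[hits$subject_id[i]]]
    slen <- nchar(subj$seq)
    s <- hits$start[i]; e <- hits$end[i]
    if (s < flank_len || e + flank_len > slen) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(row = i, subject_id = hits$subject_id[i],
                   reason = "within flank_len of contig edge",
                   stringsAsFactors = FALSE)
      next
    }
    left5 <- substr(subj$seq, s - flank_len + 1L, s)       # 5' on subject
    right3 <- substr(subj$seq, e + 1L, e + flank_len)      # 3' on subject
    if (hits$strand[i] == "+") {
      left <- left5; right <- right3
    } else {
      left <- revcomp_str(right3); right <- revcomp_str(left5)
    }
    tag <- sprintf("%s:%d-%d(%s)", hits$subject_id[i], s + 1L, e,
                   hits$strand[i])
    pairs[[length(pairs) + 1L]] <- structure(list(
      hit_row = i, hit_iv = hit_interval(hits, i),
      left = nucseq(left, id = paste0(tag, "/L")),
      right = nucseq(right, id = paste0(tag, "/R"))), class = "flank_pair")
  }
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(row = integer(), subject_id = character(),
               reason = character(), stringsAsFactors = FALSE)
  list(pairs = pairs, skipped = skipped)
}

#' Reconstruct pre-insertion sites
#'
#' Concatenates each flank pair to reform the uninterrupted target locus; the
#' insertion point bisects the result exactly.
#'
#' @param pairs List of `flank_pair` from [extract_flanks()].
#' @return List of `preinsertion_site` objects (`seq`: [nucseq] of
#'   `2*flank_len` nt, `insertion_point`, `hit_iv`), in input order.
#' @export
reconstruct_sites <- function(pairs) {
  lapply(pairs, function(p) {
    stopifnot(inherits(p, "flank_pair"))
    fl <- nchar(p$left$seq)
    stopifnot(fl == nchar(p$right$seq))
    id <- sub("/L$", "", p$left$id)
    structure(list(
      seq = nucseq(paste0(p$left$seq, p$right$seq), id = id),
      insertion_point = fl, hit_iv = p$hit_iv), class = "preinsertion_site")
  })
}

#' Deduplicate pre-insertion sites to unique insertion events
#'
#' Primary rule: exact duplicate site sequences are collapsed, keeping the
#' first occurrence. Optional secondary rule (`collapse_overlap = TRUE`):
#' sites whose IS hit intervals overlap on the same subject are also
#' collapsed regardless of sequence (the "same broader position" reading).
#' Output preserves first-occurrence order. Idempotent.
#'
#' @param sites List of `preinsertion_site`, all the same length.
#' @param collapse_overlap Also collapse coordinate-overlapping hits.
#' @return List with `sites` (kept), `n_removed_exact`, `n_removed_overlap`.
#' @export
dedup_sites <- function(sites, collapse_overlap = FALSE) {
  if (!length(sites)) {
    return(list(sites = sites, n_removed_exact = 0L, n_removed_overlap = 0L))
  }
  lens <- vapply(sites, function(s) nchar(s$seq$seq), 0L)
  if (length(unique(lens)) > 1L) stop("sites have mixed lengths")
  seqs <- vapply(sites, function(s) s$seq$seq, "")
  keep <- !duplicated(seqs)
  n_exact <- sum(!keep)
  kept <- sites[keep]
  n_overlap <- 0L
  if (collapse_overlap && length(kept) > 1L) {
    drop <- rep(FALSE, length(kept))
    for (i in seq_along(kept)[-1L]) {
      for (j in seq_len(i - 1L)) {
        if (!drop[j] && iv_overlaps(kept[[i]]$hit_iv, kept[[j]]$hit_iv)) {
          drop[i] <- TRUE
          break
        }
      }
    }
    n_overlap <- sum(drop)
    kept <- kept[!drop]
  }
  list(sites = kept, n_removed_exact = n_exact, n_removed_overlap = n_overlap)
}

#' Build the target consensus profile
#'
#' Positional stack (anchored at the insertion junction, no gapped alignment:
#' all sites are fixed-length and junction-anchored, so a gapped aligner
#' could only perturb the columns) of `logo_halfwidth` positions on each side
#' of the insertion point. Per column: A/C/G/T counts, frequencies excluding
#' `N`, and information content `IC = 2 - H`, `H = -sum f log2 f` (bits).
#' The optional small-sample correction `e_n = 3 / (2 ln2 n)` is off by
#' default so perfectly conserved columns read 2.0 bits exactly.
#'
#' @param sites List of `preinsertion_site` (>= 1).
#' @param logo_halfwidth Positions per side (default 20).
#' @param ssc Subtract the small-sample correction.
#' @param consensus_min_freq Majority-base frequency below which the
#'   consensus letter is lower-cased (default 0.5).
#' @return Object of class `consensus_profile`: `positions` (-hw..-1, 1..hw),
#'   `counts` (4 x 2hw matrix), `freqs`, `ic` (bits; `NA` for all-N columns),
#'   `n_eff`, `n_sites`, `consensus`.
#' @export
build_consensus <- function(sites, logo_halfwidth = 20L, ssc = FALSE,
                            consensus_min_freq = 0.5) {
  if (!length(sites)) stop("no sites: cannot build a consensus")
  hw <- as.integer(logo_halfwidth)
  ip <- sites[[1L]]$insertion_point
  len <- nchar(sites[[1L]]$seq$seq)
  if (hw > ip || hw > len - ip) stop("logo_halfwidth exceeds flank length")
  cols <- t(vapply(sites, function(s) {
    seq_chars(substr(s$seq$seq, ip - hw + 1L, ip + hw))
  }, character(2L * hw)))
  bases <- c("A", "C", "G", "T")
  counts <- vapply(seq_len(2L * hw), function(j) {
    tabulate(factor(cols[, j], levels = bases), nbins = 4L)
  }, numeric(4L))
  rownames(counts) <- bases
  positions <- c(seq.int(-hw, -1L), seq.int(1L, hw))
  colnames(counts) <- positions
  n_eff <- colSums(counts)
  freqs <- sweep(counts, 2L, pmax(n_eff, 1), "/")
  ic <- vapply(seq_len(ncol(counts)), function(j) {
    if (n_eff[j] == 0) return(NA_real_)
    f <- freqs[, j][freqs[, j] > 0]
    h <- -sum(f * log2(f))
    val <- 2 - h
    if (ssc) val <- val - 3 / (2 * log(2) * n_eff[j])
    val
  }, 0)
  consensus <- vapply(seq_len(ncol(counts)), function(j) {
    if (n_eff[j] == 0) return(".")
    top <- bases[which.max(freqs[, j])]
    if (freqs[top, j] < consensus_min_freq) tolower(top) else top
  }, "")
  structure(list(positions = positions, counts = counts, freqs = freqs,
                 ic = ic, n_eff = n_eff, n_sites = length(sites),
                 consensus = paste(consensus, collapse = "")),
            class = "consensus_profile")
}

#' @export
print.consensus_profile <- function(x, ...) {
  hw <- length(x$positions) %/% 2L
  cat(sprintf("<consensus_profile> %d sites, %d+%d nt around the insertion point\n",
              x$n_sites, hw, hw))
  cat("  consensus:", substr(x$consensus, 1, hw), "|",
      substr(x$consensus, hw + 1, 2 * hw), "\n")
  cat(sprintf("  mean IC %.2f bits (max %.2f)\n",
              mean(x$ic, na.rm = TRUE), max(x$ic, na.rm = TRUE)))
  invisible(x)
}

#' Export a consensus profile as a data frame
#'
#' @param x A `consensus_profile`.
#' @return Data frame: position, base counts, frequencies, bits.
#' @export
profile_table <- function(x) {
  stopifnot(inherits(x, "consensus_profile"))
  df <- data.frame(position = x$positions, t(x$counts))
  names(df)[2:5] <- c("A", "C", "G", "T")
  ft <- t(x$freqs); colnames(ft) <- c("fA", "fC", "fG", "fT")
  cbind(df, ft, n = x$n_eff, bits = x$ic,
        consensus = strsplit(x$consensus, "")[[1L]])
}

#' Run the target-mining pipeline
#'
#' Filter hits, extract flanks, reconstruct pre-insertion sites, deduplicate
#' to unique insertion events, and build the junction-anchored consensus
#' profile, with per-stage counts in a machine-readable report. Mirrors the
#' genome-mining strategy used for the IS110/IS1111 target census: all
#' genomic copies of one IS are collected, flanks of 200 bp rejoined, exact
#' duplicates removed, and a 20+20 nt logo built around the insertion point.
#'
#' @param hits A `hit_table` or a path to a tabular hit file.
#' @param subjects Named list of [nucseq] or a FASTA path.
#' @param flank_len Flank length (default 200 nt).
#' @param logo_halfwidth Logo positions per side (default 20).
#' @param pident_min,qcov_min,evalue_max,slen_min,slen_max Filters, see
#'   [filter_hits()].
#' @param collapse_overlap,ssc,consensus_min_freq Passed through.
#' @param out_dir Optional output directory (unique_sites.fasta, profile.tsv,
#'   consensus.txt, report.json).
#' @return Object of class `target_run`: `profile` (`NULL` when no unique
#'   site survived), `sites`, `report`.
#' @export
run_target_pipeline <- function(hits, subjects, flank_len = 200L,
                                logo_halfwidth = 20L, pident_min = 95,
                                qcov_min = 100, evalue_max = 0,
                                slen_min = 1e5, slen_max = 1e7,
                                collapse_overlap = FALSE, ssc = FALSE,
                                consensus_min_freq = 0.5, out_dir = NULL) {
  if (is.character(hits)) hits <- read_hits(hits)
  if (is.character(subjects)) subjects <- read_fasta(subjects)
  kept <- filter_hits(hits, pident_min = pident_min, qcov_min = qcov_min,
                      evalue_max = evalue_max, slen_min = slen_min,
                      slen_max = slen_max)
  fl <- extract_flanks(kept, subjects, flank_len = flank_len)
  sites <- reconstruct_sites(fl$pairs)
  dd <- dedup_sites(sites, collapse_overlap = collapse_overlap)
  report <- list(
    n_hits_in = nrow(hits), n_hits_kept = nrow(kept),
    filter_drops = as.list(attr(kept, "drop_counts")),
    n_flanks_extracted = length(fl$pairs),
    n_edge_skipped = nrow(fl$skipped),
    n_sites = length(sites),
    n_removed_exact = dd$n_removed_exact,
    n_removed_overlap = dd$n_removed_overlap,
    n_unique_events = length(dd$sites),
    logo = length(dd$sites) > 0L,
    low_confidence = length(dd$sites) > 0L && length(dd$sites) < 3L
  )
  profile <- if (length(dd$sites)) {
    build_consensus(dd$sites, logo_halfwidth = logo_halfwidth, ssc = ssc,
                    consensus_min_freq = consensus_min_freq)
  } else NULL
  res <- structure(list(profile = profile, sites = dd$sites, report = report),
                   class = "target_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (length(dd$sites)) {
      write_fasta(lapply(dd$sites, `[[`, "seq"),
                  file.path(out_dir, "unique_sites.fasta"))
      utils::write.table(profile_table(profile),
                         file.path(out_dir, "profile.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      writeLines(profile$consensus, file.path(out_dir, "consensus.txt"))
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  res
}

#' @export
print.target_run <- function(x, ...) {
  r <- x$report
  cat("<target_run>\n")
  cat(sprintf("  hits: %d in -> %d kept; flanks: %d (%d edge-skipped)\n",
              r$n_hits_in, r$n_hits_kept, r$n_flanks_extracted,
              r$n_edge_skipped))
  cat(sprintf("  unique insertion events: %d (removed %d exact, %d overlap)\n",
              r$n_unique_events, r$n_removed_exact, r$n_removed_overlap))
  if (is.null(x$profile)) cat("  no logo (zero unique sites)\n")
  else print(x$profile)
  if (isTRUE(r$low_confidence)) {
    cat("  warning: fewer than 3 unique events; consensus is low-confidence\n")
  }
  invisible(x)
}
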