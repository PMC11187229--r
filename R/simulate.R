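#' Random DNA string
#'
#' @param n Length in nt.
#' @param gc GC content (default 0.5).
#' @return Character string.
#' @export
random_dna <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Simulation configuration for genome implants
#'
#' States the simulated world for the target-mining benchmark: background
#' contigs with many genomic copies of one IS, each sitting inside one fixed
#' target at a stated insertion point, in one orientation per locus, with no
#' target duplication (joining the flanks of any implant reproduces the
#' uninterrupted target exactly). Defaults mirror the published mining
#' conditions at desk scale: 50 implanted copies of which 10 are exact
#' positional duplicates, 30% on the minus strand, contigs large enough to
#' pass the subject-length filter (>= 100 kb), the 12-bp target
#' `GTGAAAATACTG` split at position 6, and 200-nt flanks.
#'
#' @param seed Integer seed; a single global seed governs all draws.
#' @param n_contigs,contig_len Number and minimum length of background
#'   contigs.
#' @param is_element [nucseq] or string; `NULL` generates a random 1443-nt
#'   element (the ISEc11 length).
#' @param target,insertion_point Target top strand and its 0-based split.
#' @param n_implants Total implanted IS copies.
#' @param fraction_minus_strand Fraction of original loci on the minus
#'   strand (duplicates inherit their source strand).
#' @param n_positional_duplicates Implants that are byte-identical copies of
#'   an earlier locus (IS plus flanking context).
#' @param n_decoys Target-like strings placed without an IS.
#' @param gc Background GC content.
#' @param flank_len Margin guaranteed around every implant.
#' @param degrade_mismatches Mismatches introduced into each implanted IS
#'   copy (with `pident` adjusted accordingly) to exercise the 95% tier.
#' @return Validated list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L, n_contigs = 5L, contig_len = 120000L,
                              is_element = NULL, target = "GTGAAAATACTG",
                              insertion_point = 6L, n_implants = 50L,
                              fraction_minus_strand = 0.3,
                              n_positional_duplicates = 10L, n_decoys = 5L,
                              gc = 0.5, flank_len = 200L,
                              degrade_mismatches = 0L) {
  target <- as_nucseq(target, id = "target")
  stopifnot(n_contigs >= 1L, n_implants >= 0L, n_decoys >= 0L,
            n_positional_duplicates >= 0L,
            n_positional_duplicates <= n_implants,
            fraction_minus_strand >= 0, fraction_minus_strand <= 1,
            insertion_point >= 0L, insertion_point <= nchar(target$seq))
  if (n_positional_duplicates > 0L && n_positional_duplicates == n_implants) {
    stop("at least one original implant is needed to duplicate")
  }
  structure(list(
    seed = as.integer(seed), n_contigs = as.integer(n_contigs),
    contig_len = as.integer(contig_len), is_element = is_element,
    target = target, insertion_point = as.integer(insertion_point),
    n_implants = as.integer(n_implants),
    fraction_minus_strand = fraction_minus_strand,
    n_positional_duplicates = as.integer(n_positional_duplicates),
    n_decoys = as.integer(n_decoys), gc = gc,
    flank_len = as.integer(flank_len),
    degrade_mismatches = as.integer(degrade_mismatches)),
    class = "sim_config")
}

#' Simulate an IS-like element
#'
#' Fabricates an element with the anatomy the annotation module looks for: a
#' planted transposase ORF, a long NCR on the requested side, and (for
#' IS1111-style elements) a perfect sub-terminal inverted repeat inside the
#' 7/3-nt terminal extensions.
#'
#' @param orf_aa ORF length in amino acids (default 330, an IS1111-scale
#'   transposase).
#' @param ncr_len Long-NCR length (default 250 nt).
#' @param ncr_side `"downstream"` or `"upstream"` of the ORF.
#' @param with_stir Plant a sub-terminal inverted repeat.
#' @param stir_len Repeat length (default 12 bp).
#' @param left_ext,right_ext Terminal extension lengths.
#' @param id Element id.
#' @return A [nucseq]; attributes `orf` ([interval()]) and `stir` record the
#'   ground truth.
#' @export
simulate_is_element <- function(orf_aa = 330L, ncr_len = 250L,
                                ncr_side = c("downstream", "upstream"),
                                with_stir = TRUE, stir_len = 12L,
                                left_ext = 7L, right_ext = 3L,
                                id = "ISsim") {
  ncr_side <- match.arg(ncr_side)
  no_stop_codons <- function(s) {
    # resample any in-frame stop inside the ORF body
    repeat {
      chars <- seq_chars(s)
      starts <- seq.int(1L, length(chars) - 2L, by = 3L)
      codons <- paste0(chars[starts], chars[starts + 1L], chars[starts + 2L])
      bad <- which(codons %in% ORF_STOPS)
      if (!length(bad)) return(paste(chars, collapse = ""))
      for (b in bad) {
        chars[starts[b]] <- sample(c("C", "G"), 1L)
      }
      s <- paste(chars, collapse = "")
    }
  }
  orf <- paste0("ATG", no_stop_codons(random_dna(3L * (orf_aa - 1L))), "TAA")
  short_ncr <- random_dna(30L)
  long_ncr <- random_dna(ncr_len)
  if (ncr_side == "downstream") {
    body <- paste0(short_ncr, orf, long_ncr)
    orf_start <- nchar(short_ncr)
  } else {
    body <- paste0(long_ncr, orf, short_ncr)
    orf_start <- nchar(long_ncr)
  }
  ir <- random_dna(stir_len)
  left_block <- paste0(random_dna(left_ext), ir)
  right_block <- paste0(revcomp_str(ir), random_dna(right_ext))
  seqstr <- paste0(left_block, body, right_block)
  el <- nucseq(seqstr, id = id)
  n <- nchar(seqstr)
  attr(el, "orf") <- interval(id, left_ext + stir_len + orf_start,
                              left_ext + stir_len + orf_start + nchar(orf))
  if (with_stir) {
    attr(el, "stir") <- list(
      left = interval(id, left_ext, left_ext + stir_len),
      right = interval(id, n - right_ext - stir_len, n - right_ext))
  }
  if (!with_stir) {
    # overwrite the planted repeat blocks with plain background
    seqstr <- paste0(random_dna(left_ext + stir_len), body,
                     random_dna(stir_len + right_ext))
    el <- nucseq(seqstr, id = id)
    attr(el, "orf") <- interval(id, left_ext + stir_len + orf_start,
                                left_ext + stir_len + orf_start + nchar(orf))
  }
  el
}

degrade_seq <- function(s, n_mm) {
  if (n_mm <= 0L) return(list(seq = s, mm = 0L))
  chars <- strsplit(s, "")[[1L]]
  pos <- sample(length(chars), min(n_mm, length(chars)))
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  list(seq = paste(chars, collapse = ""), mm = length(pos))
}

#' Simulate genomes with implanted IS copies
#'
#' Generates seeded background contigs and implants the IS at `n_implants`
#' loci: at each locus the target is written, split at its insertion point,
#' and the IS inserted between the halves (no target duplication), so
#' excising the IS and rejoining the flanks reproduces the uninterrupted
#' target exactly. The requested fraction of loci is placed on the minus
#' strand (the whole cassette reverse-complemented). Positional duplicates
#' are byte-identical copies of an earlier locus including `flank_len` nt of
#' flanking context on each side, so the reconstructed pre-insertion sites
#' collapse under exact deduplication. Decoys are bare target copies without
#' an IS. Hit rows are emitted exactly as a homology search would print them
#' (1-based inclusive, `sstart > send` for minus-strand hits, `pident` 100 /
#' `qcov` 100 / `evalue` 0 unless degraded).
#'
#' @param cfg A [simulation_config()].
#' @return Object of class `sim_dataset`: `contigs` (named list of
#'   [nucseq]), `hits` (`hit_table`), `truth` (data frame: locus, contig,
#'   IS interval, strand, duplicate bookkeeping), `is_element`, `config`.
#' @export
simulate_genomes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  is_el <- if (is.null(cfg$is_element)) {
    nucseq(random_dna(1443L, cfg$gc), id = "ISsim")
  } else as_nucseq(cfg$is_element, id = "ISsim")
  n_is <- nchar(is_el$seq)
  tgt <- cfg$target$seq
  ip <- cfg$insertion_point
  fl <- cfg$flank_len

  n_orig <- cfg$n_implants - cfg$n_positional_duplicates
  orig_strands <- rep("+", max(n_orig, 0L))
  n_minus <- round(cfg$fraction_minus_strand * n_orig)
  if (n_minus > 0L) orig_strands[sample(n_orig, n_minus)] <- "-"

  make_unit <- function(strand) {
    d <- degrade_seq(is_el$seq, cfg$degrade_mismatches)
    cassette <- paste0(substr(tgt, 1L, ip), d$seq,
                       substr(tgt, ip + 1L, nchar(tgt)))
    unit <- paste0(random_dna(fl, cfg$gc), cassette, random_dna(fl, cfg$gc))
    if (strand == "-") {
      unit <- revcomp_str(unit)
      is_off <- fl + (nchar(tgt) - ip)        # offset of IS within unit
    } else {
      is_off <- fl + ip
    }
    list(seq = unit, is_off = is_off, strand = strand, mm = d$mm)
  }

  units <- lapply(orig_strands, make_unit)
  dup_of <- integer(0)
  if (cfg$n_positional_duplicates > 0L) {
    dup_of <- sample(n_orig, cfg$n_positional_duplicates, replace = TRUE)
    units <- c(units, lapply(dup_of, function(i) units[[i]]))
  }
  is_dup <- c(rep(FALSE, n_orig), rep(TRUE, cfg$n_positional_duplicates))
  dup_src <- c(rep(NA_integer_, n_orig), dup_of)

  decoy_units <- replicate(cfg$n_decoys, list(
    seq = paste0(random_dna(50L, cfg$gc), tgt, random_dna(50L, cfg$gc)),
    is_off = NA_integer_, strand = NA_character_, mm = NA_integer_),
    simplify = FALSE)

  # shuffle all placeable units across contigs, implants keeping their ids
  placement <- data.frame(
    unit = seq_along(units),
    contig = (seq_along(units) - 1L) %% cfg$n_contigs + 1L)
  contig_names <- sprintf("contig%02d", seq_len(cfg$n_contigs))
  contigs <- vector("list", cfg$n_contigs)
  truth <- list()
  hit_rows <- list()

  decoy_contig <- if (cfg$n_decoys > 0L) {
    sample(cfg$n_contigs, cfg$n_decoys, replace = TRUE)
  } else integer(0)

  for (ci in seq_len(cfg$n_contigs)) {
    parts <- character(0)
    offset <- 0L
    add <- function(s) {
      parts[[length(parts) + 1L]] <<- s
      offset <<- offset + nchar(s)
    }
    add(random_dna(sample(300:1500, 1L), cfg$gc))
    for (ui in placement$unit[placement$contig == ci]) {
      u <- units[[ui]]
      is_start <- offset + u$is_off
      add(u$seq)
      add(random_dna(sample(300:1500, 1L), cfg$gc))
      truth[[length(truth) + 1L]] <- data.frame(
        locus = ui, subject_id = contig_names[ci],
        start = is_start, end = is_start + n_is, strand = u$strand,
        is_duplicate = is_dup[ui], dup_of = dup_src[ui],
        stringsAsFactors = FALSE)
      sstart <- if (u$strand == "+") is_start + 1L else is_start + n_is
      send <- if (u$strand == "+") is_start + n_is else is_start + 1L
      pid <- round(100 * (1 - u$mm / n_is), 2)
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(
        qseqid = is_el$id, sseqid = contig_names[ci], pident = pid,
        length = n_is, mismatch = u$mm, gapopen = 0L, qstart = 1L,
        qend = n_is, sstart = sstart, send = send, evalue = 0,
        bitscore = 2 * n_is, qcovs = 100L, slen = NA_integer_,
        stringsAsFactors = FALSE)
    }
    for (di in which(decoy_contig == ci)) {
      add(decoy_units[[di]]$seq)
      add(random_dna(sample(300:1500, 1L), cfg$gc))
    }
    if (offset < cfg$contig_len) add(random_dna(cfg$contig_len - offset, cfg$gc))
    contigs[[ci]] <- nucseq(paste(parts, collapse = ""), id = contig_names[ci])
  }
  names(contigs) <- contig_names

  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(locus = integer(), subject_id = character(), start = integer(),
               end = integer(), strand = character(), is_duplicate = logical(),
               dup_of = integer())
  hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else NULL
  if (!is.null(hits)) {
    slen_by <- vapply(contigs, function(x) nchar(x$seq), 0L)
    hits$slen <- slen_by[hits$sseqid]
    hits <- normalize_hits(hits)
  }
  structure(list(contigs = contigs, hits = hits, truth = truth,
                 is_element = is_el, config = cfg), class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d contig(s), %d implant(s) (%d duplicates), IS %d nt\n",
              length(x$contigs), nrow(x$truth), sum(x$truth$is_duplicate),
              nchar(x$is_element$seq)))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' @param ds A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly. Writes `contigs.fasta`, `is.fasta`,
#'   `hits.tsv`, `truth.tsv`.
#' @export
write_sim_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(ds$contigs, file.path(dir, "contigs.fasta"))
  write_fasta(ds$is_element, file.path(dir, "is.fasta"))
  write_hits(ds$hits, file.path(dir, "hits.tsv"))
  utils::write.table(ds$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Simulate a seekRNA with planted target-complementary segments
#'
#' Emits a seekRNA containing the antiparallel complements of a top-strand
#' window (T segment) and a bottom-strand window (B segment) of the target,
#' embedded in random scaffold in the requested 5'->3' order. The windows
#' may overlap in the target (as the natural matches do). Scaffold draws are
#' rejected and resampled (bounded retries) when they would create a
#' spurious exact match of `min_guard` nt or longer, or extend a planted
#' segment, so the planted spans are exactly the maximal matches a scanner
#' should report.
#'
#' @param target A [nucseq]: target top strand.
#' @param insertion_point 0-based insertion point (windows must straddle it).
#' @param t_window,b_window Length-2 integer vectors `c(start, end)`
#'   (0-based half-open) on the target top strand.
#' @param scaffold_len Scaffold length before/between/after the segments
#'   (default 10; 0 gives the two complements exactly abutted).
#' @param order `"TB"` (IS1111-style) or `"BT"` (IS110-style).
#' @param min_guard Spurious-match guard length (default 7).
#' @param seed Optional seed (`NULL` leaves the RNG stream untouched).
#' @return Object of class `sim_seekrna`: `seekrna` ([nucseq]), `t_rna_span`,
#'   `b_rna_span` (0-based half-open ground-truth spans), `order`.
#' @export
simulate_seekrna <- function(target, insertion_point, t_window, b_window,
                             scaffold_len = 10L, order = c("TB", "BT"),
                             min_guard = 7L, seed = NULL) {
  order <- match.arg(order)
  if (!is.null(seed)) set.seed(seed)
  target <- as_nucseq(target, id = "target")
  nt <- nchar(target$seq)
  chk_win <- function(w, label) {
    if (w[1L] < 0L || w[2L] > nt || w[2L] <= w[1L]) {
      stop(label, " window outside the target")
    }
    if (!(w[1L] < insertion_point && insertion_point < w[2L] ||
          w[1L] <= insertion_point && insertion_point <= w[2L])) {
      stop(label, " window must straddle the insertion point")
    }
  }
  chk_win(t_window, "t"); chk_win(b_window, "b")
  t_seg <- revcomp_str(substr(target$seq, t_window[1L] + 1L, t_window[2L]))
  b_seg <- substr(target$seq, b_window[1L] + 1L, b_window[2L])
  segs <- if (order == "TB") list(t_seg, b_seg) else list(b_seg, t_seg)
  guard <- min(min_guard, nchar(t_seg), nchar(b_seg))

  for (attempt in seq_len(100L)) {
    sc <- replicate(3L, random_dna(scaffold_len), simplify = TRUE)
    rna <- paste0(sc[1L], segs[[1L]], sc[2L], segs[[2L]], sc[3L])
    first_span <- c(scaffold_len, scaffold_len + nchar(segs[[1L]]))
    second_start <- first_span[2L] + scaffold_len
    second_span <- c(second_start, second_start + nchar(segs[[2L]]))
    if (order == "TB") {
      t_span <- first_span; b_span <- second_span
    } else {
      b_span <- first_span; t_span <- second_span
    }
    if (scaffold_len == 0L) break          # abutted form: no guard possible
    sr <- seq_chars(rna)
    t_hits <- maximal_matches(sr, seq_chars(revcomp(target)), guard, 0L)
    b_hits <- maximal_matches(sr, seq_chars(target), guard, 0L)
    span_of <- function(h) c(h$a_start, h$a_start + h$length)
    ok <- length(t_hits) == 1L && length(b_hits) == 1L &&
      identical(span_of(t_hits[[1L]]), as.integer(t_span)) &&
      identical(span_of(b_hits[[1L]]), as.integer(b_span))
    if (ok) break
    if (attempt == 100L) stop("could not place scaffold without spurious matches")
  }
  structure(list(
    seekrna = nucseq(rna, id = "sim_seekrna", is_rna = TRUE),
    t_rna_span = as.integer(t_span), b_rna_span = as.integer(b_span),
    order = order, target = target, insertion_point = insertion_point),
    class = "sim_seekrna")
}

#' Simulate small-RNA read coverage over an element
#'
#' Emulates the coverage shape seen for transposase-associated RNAs: a
#' predominant short "peak" form inside a longer precursor-like span. Peak
#' reads tile the peak window with up to `read_len_jitter` nt trimmed
#' independently from each end; long-form reads do the same over the long
#' window. Defaults state the published world: 150 peak reads over an 82-nt
#' window and 50 long reads over a 154-nt superset.
#'
#' @param ref_len Reference length.
#' @param peak_span,long_span Length-2 `c(start, end)`, 0-based half-open;
#'   `peak_span` must lie within `long_span`, which must lie within the
#'   reference.
#' @param n_peak_reads,n_long_reads Read counts (defaults 150 and 50).
#' @param read_len_jitter Maximum nt trimmed from each read end (default 3).
#' @param seed Optional seed.
#' @return Data frame of read intervals (`subject_id`, `start`, `end`),
#'   usable directly by [call_peak()] or [write_bed()].
#' @export
simulate_coverage <- function(ref_len, peak_span = c(60L, 142L),
                              long_span = c(30L, 184L), n_peak_reads = 150L,
                              n_long_reads = 50L, read_len_jitter = 3L,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!(long_span[1L] >= 0L && long_span[2L] <= ref_len)) {
    stop("long_span outside [0, ref_len)")
  }
  if (!(peak_span[1L] >= long_span[1L] && peak_span[2L] <= long_span[2L])) {
    stop("peak_span must lie within long_span")
  }
  draw <- function(n, span) {
    if (n <= 0L) return(NULL)
    j1 <- sample.int(read_len_jitter + 1L, n, replace = TRUE) - 1L
    j2 <- sample.int(read_len_jitter + 1L, n, replace = TRUE) - 1L
    data.frame(subject_id = "element", start = span[1L] + j1,
               end = span[2L] - j2, stringsAsFactors = FALSE)
  }
  out <- rbind(draw(n_peak_reads, peak_span), draw(n_long_reads, long_span))
  if (is.null(out) || !nrow(out)) stop("no reads requested")
  out[sample(nrow(out)), , drop = FALSE]
}
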