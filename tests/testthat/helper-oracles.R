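# Independent oracles, deliberately written with the crudest possible logic
# (per-base loops, exhaustive enumeration) and no reuse of package internals.

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

oracle_revcomp <- function(s) {
  chars <- strsplit(s, "")[[1L]]
  out <- character(length(chars))
  for (k in seq_along(chars)) {
    out[length(chars) - k + 1L] <- COMP[[chars[k]]]
  }
  paste(out, collapse = "")
}

# Watson-Crick pair test for a single base pair (DNA space, no wobble)
oracle_pairs <- function(a, b) {
  !is.na(a) && !is.na(b) && a != "N" && b != "N" && COMP[[a]] == b
}

# entropy-based information content of one column of base counts
oracle_ic <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(NA_real_)
  h <- 0
  for (c in counts) {
    if (c > 0) {
      f <- c / n
      h <- h - f * log2(f)
    }
  }
  2 - h
}

# global longest stop-terminated ORF by walking from every start codon
oracle_orf <- function(s, min_aa) {
  starts <- c("ATG", "GTG", "TTG")
  stops <- c("TAA", "TAG", "TGA")
  n <- nchar(s)
  cands <- list()
  for (strand in c("+", "-")) {
    str <- if (strand == "+") s else oracle_revcomp(s)
    for (p in seq_len(n - 2L)) {
      if (!substr(str, p, p + 2L) %in% starts) next
      q <- p + 3L
      while (q + 2L <= n) {
        if (substr(str, q, q + 2L) %in% stops) {
          aa <- (q - p) / 3L
          if (aa >= min_aa) {
            st0 <- p - 1L
            en0 <- q + 2L
            if (strand == "-") {
              tmp <- st0
              st0 <- n - en0
              en0 <- n - tmp
            }
            cands[[length(cands) + 1L]] <-
              list(start = st0, end = en0, strand = strand, aa = aa)
          }
          break
        }
        q <- q + 3L
      }
    }
  }
  if (!length(cands)) return(NULL)
  lens <- vapply(cands, function(o) o$end - o$start, 0)
  plus <- vapply(cands, function(o) o$strand == "+", TRUE)
  st <- vapply(cands, function(o) o$start, 0)
  cands[[order(-lens, !plus, st)[1L]]]
}

# exhaustive all-pairs sub-terminal inverted repeat search with the same
# window/terminal-pair definition, coded from scratch
oracle_stir <- function(s, min_ir = 11L, max_mm = 1L, left_ext = 7L,
                        right_ext = 3L, window = 30L) {
  n <- nchar(s)
  window <- min(window, (n - left_ext - right_ext) %/% 2L)
  best <- NULL
  for (L in seq.int(window, min_ir)) {
    found <- list()
    for (i in 0:(window - L)) {
      lseg <- substr(s, left_ext + i + 1L, left_ext + i + L)
      for (j in 0:(window - L)) {
        r0 <- n - right_ext - window + j
        rseg <- substr(s, r0 + 1L, r0 + L)
        rc <- oracle_revcomp(rseg)
        lv <- strsplit(lseg, "")[[1L]]
        rv <- strsplit(rc, "")[[1L]]
        pair <- lv == rv & lv != "N" & rv != "N"
        mm <- sum(!pair)
        if (mm <= max_mm && pair[1L] && pair[L]) {
          found[[length(found) + 1L]] <-
            list(li = left_ext + i, ri = r0, L = L, mm = mm,
                 outer = i + (window - j - L), i = i)
        }
      }
    }
    if (length(found)) {
      o <- order(vapply(found, `[[`, 0, "mm"),
                 vapply(found, `[[`, 0, "outer"),
                 vapply(found, `[[`, 0, "i"))
      best <- found[[o[1L]]]
      break
    }
  }
  best
}

# exhaustive maximal approximate substring matches of rna against a literal
# pattern: all (i, j, L) windows, maximality checked by explicit extension
oracle_substring_matches <- function(rna, pat, min_len, max_mm) {
  rv <- strsplit(rna, "")[[1L]]
  pv <- strsplit(pat, "")[[1L]]
  n <- length(rv)
  m <- length(pv)
  mmcount <- function(i, j, L) {
    a <- rv[i:(i + L - 1L)]
    b <- pv[j:(j + L - 1L)]
    sum(a != b | a == "N" | b == "N")
  }
  out <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      max_L <- min(n - i + 1L, m - j + 1L)
      if (max_L < min_len) next
      for (L in seq.int(min_len, max_L)) {
        if (mmcount(i, j, L) > max_mm) next
        left_ok <- i == 1L || j == 1L || mmcount(i - 1L, j - 1L, L + 1L) > max_mm
        right_ok <- i + L > n || j + L > m || mmcount(i, j, L + 1L) > max_mm
        if (left_ok && right_ok) {
          out[[length(out) + 1L]] <-
            c(i0 = i - 1L, j0 = j - 1L, L = L, mm = mmcount(i, j, L))
        }
      }
    }
  }
  if (!length(out)) {
    return(matrix(integer(), ncol = 4L,
                  dimnames = list(NULL, c("i0", "j0", "L", "mm"))))
  }
  mat <- do.call(rbind, out)
  unique(mat[order(mat[, "i0"], mat[, "j0"], mat[, "L"]), , drop = FALSE])
}

# convert a scan_report match table into the oracle's (i0, j0, L, mm) layout
scan_to_oracle <- function(df, strand, target_len) {
  if (!nrow(df)) {
    return(matrix(integer(), ncol = 4L,
                  dimnames = list(NULL, c("i0", "j0", "L", "mm"))))
  }
  j0 <- if (strand == "T") target_len - df$target_end else df$target_start
  mat <- cbind(i0 = df$rna_start, j0 = j0, L = df$length, mm = df$mismatches)
  mat[order(mat[, "i0"], mat[, "j0"], mat[, "L"]), , drop = FALSE]
}

# verify one reported match base by base: every position either forms a
# Watson-Crick pair with the stated target strand or counts as a mismatch
oracle_verify_match <- function(rna_seq, target_seq, m, strand) {
  rv <- strsplit(rna_seq, "")[[1L]]
  tv <- strsplit(target_seq, "")[[1L]]
  nt <- length(tv)
  mm <- 0L
  for (k in seq_len(m$length)) {
    rb <- rv[m$rna_start + k]
    tb <- if (strand == "T") {
      tv[m$target_end - k + 1L]        # antiparallel along the top strand
    } else {
      COMP[[tv[m$target_start + k]]]   # bottom-strand base at top coords
    }
    if (strand == "B") {
      # antiparallel along the bottom strand: reverse traversal in bottom
      # coordinates corresponds to forward traversal in top coordinates
      tb <- COMP[[tv[m$target_start + k]]]
      if (!oracle_pairs(rb, tb)) mm <- mm + 1L
    } else {
      if (!oracle_pairs(rb, tb)) mm <- mm + 1L
    }
  }
  mm == m$mismatches
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# sample a new reprogramming target compatible with the original match
# footprint: same length and insertion point, and such that a seekRNA whose
# match windows are rewritten for it (simulated here with independent string
# code) carries exactly the two planted complementary segments -- no
# accidental extension into the scaffold, no spurious extra match. The check
# uses the exhaustive substring oracle, not the package scanner.
compatible_reprogram_target <- function(rna_seq, rep0, len, min_len = 7L,
                                        max_tries = 200L) {
  ts <- rep0$best_t$target_start; te <- rep0$best_t$target_end
  bs <- rep0$best_b$target_start; be <- rep0$best_b$target_end
  t_i <- rep0$best_t$rna_start; t_L <- rep0$best_t$length
  b_i <- rep0$best_b$rna_start; b_L <- rep0$best_b$length
  for (try in seq_len(max_tries)) {
    cand <- random_seq(len)
    chars <- strsplit(rna_seq, "")[[1L]]
    t_repl <- strsplit(oracle_revcomp(substr(cand, ts + 1L, te)), "")[[1L]]
    b_repl <- strsplit(substr(cand, bs + 1L, be), "")[[1L]]
    chars[t_i + seq_len(t_L)] <- t_repl
    chars[b_i + seq_len(b_L)] <- b_repl
    new_rna <- paste(chars, collapse = "")
    tm <- oracle_substring_matches(new_rna, oracle_revcomp(cand), min_len, 0L)
    bm <- oracle_substring_matches(new_rna, cand, min_len, 0L)
    ok <- nrow(tm) == 1L && nrow(bm) == 1L &&
      tm[1L, "i0"] == t_i && tm[1L, "L"] == t_L &&
      bm[1L, "i0"] == b_i && bm[1L, "L"] == b_L
    if (ok) return(cand)
  }
  stop("no compatible target found")
}
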