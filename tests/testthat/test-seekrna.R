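test_that("scan_seekrna finds constructed T and B segments in order", {
  target <- "GATCCATGGTCAAGTGCCTA"                     # 20 nt, fixed
  tseg <- oracle_revcomp(substr(target, 1, 10))        # pairs with top strand
  bseg <- substr(target, 11, 20)                       # pairs with bottom strand
  rna <- paste0(tseg, "AACCAA", bseg)
  rep <- scan_seekrna(nucseq(rna, id = "r"), nucseq(target, id = "t"),
                      min_match_len = 7)
  expect_equal(nrow(rep$t_matches), 1L)
  expect_equal(nrow(rep$b_matches), 1L)
  expect_equal(unlist(rep$best_t[c("rna_start", "rna_end")]),
               c(rna_start = 0L, rna_end = 10L))
  expect_equal(unlist(rep$best_t[c("target_start", "target_end")]),
               c(target_start = 0L, target_end = 10L))
  expect_equal(unlist(rep$best_b[c("rna_start", "rna_end")]),
               c(rna_start = 16L, rna_end = 26L))
  expect_equal(unlist(rep$best_b[c("target_start", "target_end")]),
               c(target_start = 10L, target_end = 20L))
  expect_equal(rep$order, "T-before-B")
  expect_equal(classify_family_by_order(rep), "IS1111-pattern")

  # same two segments in the opposite order
  rep2 <- scan_seekrna(nucseq(paste0(bseg, "AACCAA", tseg), id = "r2"),
                       nucseq(target, id = "t"), min_match_len = 7)
  expect_equal(rep2$order, "B-before-T")
  expect_equal(classify_family_by_order(rep2), "IS110-pattern")

  # RNA input with U is handled identically
  rna_u <- chartr("T", "U", rna)
  rep_u <- scan_seekrna(nucseq(rna_u, id = "ru"), nucseq(target, id = "t"),
                        min_match_len = 7)
  expect_equal(rep_u$order, "T-before-B")

  expect_error(scan_seekrna(nucseq("ACGT", id = "s"), nucseq(target, id = "t"),
                            min_match_len = 7), "shorter than min_match_len")
  # one-sided match: order undetermined
  rep1 <- scan_seekrna(nucseq(paste0(tseg, "AACCAA"), id = "r1"),
                       nucseq(target, id = "t"), min_match_len = 7)
  expect_equal(rep1$order, "undetermined")
  expect_equal(classify_family_by_order(rep1), "undetermined")
})

test_that("simulated seekRNAs are recovered with ground-truth spans", {
  target <- "GTGAAAATACTG"
  for (ord in c("TB", "BT")) {
    sim <- simulate_seekrna(target, 6L, t_window = c(1L, 9L),
                            b_window = c(3L, 12L), scaffold_len = 12L,
                            order = ord, seed = 7 + (ord == "BT"))
    rep <- scan_seekrna(sim$seekrna, target, min_match_len = 7,
                        insertion_point = 6L)
    expect_equal(c(rep$best_t$rna_start, rep$best_t$rna_end), sim$t_rna_span)
    expect_equal(c(rep$best_b$rna_start, rep$best_b$rna_end), sim$b_rna_span)
    expect_equal(rep$order, if (ord == "TB") "T-before-B" else "B-before-T")
    expect_true(rep$overlap_in_target)      # windows 1..9 and 3..12 intersect
    expect_true(rep$insertion_point_covered)
  }
})

test_that("every reported match re-verifies base by base and is maximal", {
  set.seed(37)
  for (k in 1:15) {
    target <- random_seq(sample(12:30, 1))
    rna <- random_seq(sample(40:120, 1))
    # ensure at least some signal: splice in a complement of a target window
    w <- sort(sample(nchar(target), 2))
    if (w[2] - w[1] >= 6) {
      seg <- oracle_revcomp(substr(target, w[1], w[2]))
      pos <- sample(nchar(rna) - nchar(seg), 1)
      rna <- paste0(substr(rna, 1, pos), seg,
                    substr(rna, pos + nchar(seg) + 1, nchar(rna)))
    }
    mm_allowed <- sample(0:1, 1)
    rep <- scan_seekrna(nucseq(rna, id = "r"), nucseq(target, id = "t"),
                        min_match_len = 7, max_mismatch = mm_allowed)
    ttop <- target
    tbot <- oracle_revcomp(target)
    # T matches are substrings of the bottom strand; B of the top strand
    expect_equal(scan_to_oracle(rep$t_matches, "T", nchar(target)),
                 oracle_substring_matches(rna, tbot, 7, mm_allowed))
    expect_equal(scan_to_oracle(rep$b_matches, "B", nchar(target)),
                 oracle_substring_matches(rna, ttop, 7, mm_allowed))
    for (i in seq_len(nrow(rep$t_matches))) {
      expect_true(oracle_verify_match(rna, target, rep$t_matches[i, ], "T"))
    }
    for (i in seq_len(nrow(rep$b_matches))) {
      expect_true(oracle_verify_match(rna, target, rep$b_matches[i, ], "B"))
    }
  }
})

test_that("scanning is symmetric under target reverse complement with T/B swap", {
  set.seed(43)
  for (k in 1:10) {
    target <- random_seq(20)
    sim <- simulate_seekrna(target, 10L, t_window = c(4L, 13L),
                            b_window = c(8L, 17L), scaffold_len = 8L)
    rep_f <- scan_seekrna(sim$seekrna, target, min_match_len = 7)
    rep_r <- scan_seekrna(sim$seekrna, revcomp(target), min_match_len = 7)
    nt <- nchar(target)
    flip <- function(df) {
      out <- df
      out$target_start <- nt - df$target_end
      out$target_end <- nt - df$target_start
      out[order(out$rna_start, out$target_start), ]
    }
    # T matches against the reverse complement are the B matches, flipped
    expect_equal(unname(as.matrix(flip(rep_r$t_matches))),
                 unname(as.matrix(rep_f$b_matches)))
    expect_equal(unname(as.matrix(flip(rep_r$b_matches))),
                 unname(as.matrix(rep_f$t_matches)))
  }
})

test_that("call_peak thresholds contiguous coverage runs", {
  # toy coverage profile [0,0,5,5,5,1,0] on a 7-nt reference
  reads <- data.frame(start = c(rep(2, 5), 5), end = c(rep(5, 5), 6))
  pk <- call_peak(reads, ref_len = 7, alpha = 0.5)
  expect_equal(pk$coverage, c(0, 0, 5, 5, 5, 1, 0))
  expect_equal(c(pk$peak$start, pk$peak$end), c(2, 5))
  expect_equal(pk$peak_len, 3L)

  # identical reads: peak equals the read exactly
  same <- data.frame(start = rep(10, 20), end = rep(92, 20))
  pk2 <- call_peak(same, ref_len = 120)
  expect_equal(c(pk2$peak$start, pk2$peak$end), c(10, 92))
  expect_equal(pk2$long_len, pk2$peak_len)

  # invariance to interval order
  set.seed(47)
  reads3 <- simulate_coverage(250, c(60, 142), c(30, 184), seed = 3)
  pk_a <- call_peak(reads3, ref_len = 250)
  pk_b <- call_peak(reads3[rev(seq_len(nrow(reads3))), ], ref_len = 250)
  expect_equal(pk_a$coverage, pk_b$coverage)
  expect_equal(pk_a$peak_len, pk_b$peak_len)

  # ORF-relative reporting
  pk3 <- call_peak(same, ref_len = 120, orf_end = 5)
  expect_equal(unname(pk3$peak_rel), c(5, 87))

  expect_error(call_peak(data.frame(start = integer(), end = integer())),
               "no read intervals")
})

test_that("simulated coverage reproduces the peak and long-form sizes", {
  reads <- simulate_coverage(250, peak_span = c(60, 142),
                             long_span = c(30, 184), n_peak_reads = 150,
                             n_long_reads = 50, seed = 11)
  pk <- call_peak(reads, ref_len = 250)
  expect_true(abs(pk$peak_len - 82) <= 3)
  expect_true(abs(pk$long_len - 154) <= 5)
  # degenerate mixes
  only_long <- simulate_coverage(250, c(60, 142), c(30, 184),
                                 n_peak_reads = 0, n_long_reads = 40,
                                 read_len_jitter = 0, seed = 12)
  pk_l <- call_peak(only_long, ref_len = 250)
  expect_equal(c(pk_l$peak$start, pk_l$peak$end), c(30, 184))
  expect_equal(pk_l$peak_len, pk_l$long_len)
  no_long <- simulate_coverage(250, c(60, 142), c(30, 184),
                               n_long_reads = 0, read_len_jitter = 0, seed = 13)
  pk_n <- call_peak(no_long, ref_len = 250)
  expect_equal(pk_n$long_len, pk_n$peak_len)
  expect_error(simulate_coverage(100, c(10, 60), c(5, 120)), "long_span")
  expect_error(simulate_coverage(250, c(10, 200), c(30, 184)), "peak_span")
})
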