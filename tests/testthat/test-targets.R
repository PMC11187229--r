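fake_hits <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    defaults <- list(qseqid = "IS1", sseqid = "ctg", pident = 100,
                     length = 1401, mismatch = 0, gapopen = 0, qstart = 1,
                     qend = 1401, sstart = 1000, send = 2400, evalue = 0,
                     bitscore = 2000, qcovs = 100, slen = 5e6)
    as.data.frame(utils::modifyList(defaults, r), stringsAsFactors = FALSE)
  }))
  isseek:::normalize_hits(df)
}

test_that("filter_hits applies the published stringency tiers", {
  h <- fake_hits(list(pident = 96.2), list(pident = 100),
                 list(slen = 50000), list(qcovs = 99), list(evalue = 1e-30))
  kept95 <- filter_hits(h, pident_min = 95)
  expect_equal(kept95$pident, c(96.2, 100))
  kept100 <- filter_hits(h, pident_min = 100)
  expect_equal(kept100$pident, 100)           # 96.2 dropped at the 100 tier
  drops <- attr(filter_hits(h), "drop_counts")
  expect_equal(unname(drops["slen"]), 1)      # subject length >= 100,000
  expect_equal(unname(drops["qcov"]), 1)      # query coverage 100 required
  expect_equal(unname(drops["evalue"]), 1)    # E value of 0 required
})

test_that("raising pident_min never increases the number of kept hits", {
  set.seed(13)
  h <- do.call(fake_hits, lapply(1:40, function(i) {
    list(pident = round(stats::runif(1, 90, 100), 2))
  }))
  counts <- vapply(c(90, 92, 95, 97, 99, 100),
                   function(p) nrow(filter_hits(h, pident_min = p)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("extract_flanks honours coordinates, strand and contig edges", {
  set.seed(17)
  contig <- nucseq(random_seq(10000), id = "ctg")
  h <- fake_hits(list(sstart = 1001, send = 2400, slen = 10000))
  fl <- extract_flanks(h, list(ctg = contig), flank_len = 200)
  expect_length(fl$pairs, 1L)
  p <- fl$pairs[[1]]
  expect_equal(p$left$seq, substr(contig$seq, 801, 1000))
  expect_equal(p$right$seq, substr(contig$seq, 2401, 2600))

  # minus-strand oracle: reverse-complement the whole contig, recompute on the
  # plus strand, and compare
  hm <- fake_hits(list(sstart = 2400, send = 1001, slen = 10000))
  flm <- extract_flanks(hm, list(ctg = contig), flank_len = 200)
  rc <- nucseq(oracle_revcomp(contig$seq), id = "ctg")
  # the hit occupies [1000,2400) forward = [7600,9000) on the reverse
  h_rc <- fake_hits(list(sstart = 7601, send = 9000, slen = 10000))
  fl_rc <- extract_flanks(h_rc, list(ctg = rc), flank_len = 200)
  expect_equal(flm$pairs[[1]]$left$seq, fl_rc$pairs[[1]]$left$seq)
  expect_equal(flm$pairs[[1]]$right$seq, fl_rc$pairs[[1]]$right$seq)

  # too close to the edge: skipped with a logged reason, not padded
  he <- fake_hits(list(sstart = 51, send = 1451, slen = 10000))
  fle <- extract_flanks(he, list(ctg = contig), flank_len = 200)
  expect_length(fle$pairs, 0L)
  expect_equal(nrow(fle$skipped), 1L)
  expect_match(fle$skipped$reason, "edge")

  expect_error(extract_flanks(h, list(other = contig)), "missing.*ctg")
})

test_that("reconstruct_sites concatenates flanks around the junction", {
  left <- nucseq(strrep("A", 200), id = "x/L")
  right <- nucseq(strrep("C", 200), id = "x/R")
  pair <- structure(list(hit_row = 1L, hit_iv = interval("c", 0, 10),
                         left = left, right = right), class = "flank_pair")
  sites <- reconstruct_sites(list(pair, pair, pair))
  expect_length(sites, 3L)
  s <- sites[[1]]
  expect_equal(nchar(s$seq$seq), 400L)
  expect_equal(s$insertion_point, 200L)
  expect_equal(substr(s$seq$seq, 200, 201), "AC")
  expect_length(reconstruct_sites(list()), 0L)
})

make_site <- function(seq, iv) {
  structure(list(seq = nucseq(seq, id = "s"), insertion_point = nchar(seq) %/% 2,
                 hit_iv = iv), class = "preinsertion_site")
}

test_that("dedup_sites collapses exact duplicates and is idempotent", {
  set.seed(19)
  a <- random_seq(40); b <- random_seq(40)
  a_snp <- paste0("T", substr(a, 2, 40))
  if (a_snp == a) a_snp <- paste0("G", substr(a, 2, 40))
  s1 <- make_site(a, interval("c1", 100, 200))
  s1copy <- make_site(a, interval("c1", 100, 200))
  s2 <- make_site(b, interval("c2", 100, 200))
  dd <- dedup_sites(list(s1, s1copy, s2))
  expect_length(dd$sites, 2L)
  expect_equal(dd$n_removed_exact, 1L)
  expect_equal(dd$sites[[1]]$seq$seq, a)      # first occurrence kept

  # one-base difference: both kept under the primary rule
  s3 <- make_site(a_snp, interval("c1", 150, 250))
  dd2 <- dedup_sites(list(s1, s3))
  expect_length(dd2$sites, 2L)
  # ... collapsed only when coordinate-overlap collapse is requested
  dd3 <- dedup_sites(list(s1, s3), collapse_overlap = TRUE)
  expect_length(dd3$sites, 1L)
  expect_equal(dd3$n_removed_overlap, 1L)
  # non-overlapping intervals survive overlap collapse
  s4 <- make_site(a_snp, interval("c1", 900, 1000))
  expect_length(dedup_sites(list(s1, s4), collapse_overlap = TRUE)$sites, 2L)

  # idempotence
  once <- dedup_sites(list(s1, s1copy, s2, s3), collapse_overlap = TRUE)
  twice <- dedup_sites(once$sites, collapse_overlap = TRUE)
  expect_equal(vapply(twice$sites, function(s) s$seq$seq, ""),
               vapply(once$sites, function(s) s$seq$seq, ""))
  expect_equal(twice$n_removed_exact + twice$n_removed_overlap, 0L)

  expect_error(dedup_sites(list(s1, make_site(random_seq(30),
                                              interval("c", 0, 1)))),
               "mixed lengths")
})

test_that("build_consensus computes frequencies and information content", {
  set.seed(23)
  site <- random_seq(40)
  sites <- lapply(1:10, function(i) make_site(site, interval("c", i, i + 1)))
  prof <- build_consensus(sites, logo_halfwidth = 20)
  expect_equal(prof$n_sites, 10L)
  expect_true(all(prof$ic == 2.0))            # perfectly conserved columns
  expect_equal(prof$consensus, site)
  expect_equal(unname(colSums(prof$freqs)), rep(1, 40))

  # a uniform column carries 0 bits
  seqs <- vapply(c("A", "C", "G", "T"), function(b) {
    paste0(substr(site, 1, 19), b, substr(site, 21, 40))
  }, "")
  prof_u <- build_consensus(lapply(seqs, make_site, iv = interval("c", 0, 1)))
  expect_equal(prof_u$ic[20], 0)
  expect_true(all(prof_u$ic[-20] == 2))

  # skewed column: compare against the direct entropy oracle
  mix <- c(rep("A", 6), rep("G", 2), "C", "T")
  seqs2 <- vapply(mix, function(b) {
    paste0(substr(site, 1, 19), b, substr(site, 21, 40))
  }, "")
  prof_s <- build_consensus(lapply(seqs2, make_site, iv = interval("c", 0, 1)))
  expect_equal(prof_s$ic[20], oracle_ic(c(A = 6, C = 1, G = 2, T = 1)))
  # majority 6/10 >= 0.5 -> upper case consensus letter
  expect_equal(substr(prof_s$consensus, 20, 20), "A")
  # majority below 0.5 -> lower case
  mix4 <- c(rep("A", 4), rep("G", 3), rep("C", 2), "T")
  seqs4 <- vapply(mix4, function(b) {
    paste0(substr(site, 1, 19), b, substr(site, 21, 40))
  }, "")
  prof4 <- build_consensus(lapply(seqs4, make_site, iv = interval("c", 0, 1)))
  expect_equal(substr(prof4$consensus, 20, 20), "a")

  # small-sample correction shifts every defined column by 3/(2 ln2 n)
  prof_c <- build_consensus(lapply(seqs2, make_site, iv = interval("c", 0, 1)),
                            ssc = TRUE)
  expect_equal(prof_s$ic - prof_c$ic, rep(3 / (2 * log(2) * 10), 40))

  # an all-N column is reported as missing
  seqs3 <- rep(paste0(substr(site, 1, 19), "N", substr(site, 21, 40)), 3)
  prof_n <- build_consensus(lapply(seqs3, make_site, iv = interval("c", 0, 1)))
  expect_true(is.na(prof_n$ic[20]))
  expect_equal(substr(prof_n$consensus, 20, 20), ".")

  expect_error(build_consensus(list()), "no sites")
})

test_that("information content matches the oracle on many random columns", {
  set.seed(29)
  for (k in 1:200) {
    counts <- stats::rmultinom(1, sample(1:100, 1), stats::runif(4, 0.01, 1))[, 1]
    names(counts) <- c("A", "C", "G", "T")
    sites <- unlist(lapply(names(counts), function(b) {
      rep(b, counts[[b]])
    }))
    sites <- lapply(sites, function(b) {
      make_site(paste0("A", b, "CG"), interval("c", 0, 1))
    })
    prof <- build_consensus(sites, logo_halfwidth = 2)
    expect_equal(prof$ic[2], oracle_ic(counts), tolerance = 1e-12)
  }
})

test_that("the mining pipeline recovers an implanted target end to end", {
  cfg <- simulation_config(seed = 101, n_implants = 12,
                           n_positional_duplicates = 2, n_decoys = 2,
                           n_contigs = 2)
  ds <- simulate_genomes(cfg)
  res <- run_target_pipeline(ds$hits, ds$contigs)
  expect_equal(res$report$n_unique_events, 10L)
  expect_equal(substr(res$profile$consensus, 15, 26), "GTGAAAATACTG")
  # all implants at one locus -> single unique event, low-confidence logo
  cfg1 <- simulation_config(seed = 102, n_implants = 5,
                            n_positional_duplicates = 4, n_decoys = 0,
                            n_contigs = 1, fraction_minus_strand = 0)
  res1 <- run_target_pipeline(simulate_genomes(cfg1)$hits,
                              simulate_genomes(cfg1)$contigs)
  expect_equal(res1$report$n_unique_events, 1L)
  expect_true(res1$report$low_confidence)
  expect_equal(res1$profile$n_sites, 1L)
})

test_that("the consensus profile is invariant under whole-contig reverse complement", {
  cfg <- simulation_config(seed = 103, n_implants = 15,
                           n_positional_duplicates = 0, n_contigs = 2,
                           fraction_minus_strand = 0.4)
  ds <- simulate_genomes(cfg)
  res <- run_target_pipeline(ds$hits, ds$contigs)
  # flip every contig and every hit coordinate accordingly
  rc_contigs <- lapply(ds$contigs, function(x) {
    structure(list(id = x$id, seq = oracle_revcomp(x$seq), is_rna = FALSE),
              class = "nucseq")
  })
  raw_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
                "qstart", "qend", "sstart", "send", "evalue", "bitscore",
                "qcovs", "slen")
  h <- as.data.frame(ds$hits)[raw_cols]
  W <- vapply(ds$contigs, function(x) nchar(x$seq), 0L)[h$sseqid]
  tmp <- W - h$sstart + 1L
  h$send <- W - h$send + 1L
  h$sstart <- tmp
  h_rc <- isseek:::normalize_hits(h)
  res_rc <- run_target_pipeline(h_rc, rc_contigs)
  expect_equal(res_rc$report$n_unique_events, res$report$n_unique_events)
  expect_equal(res_rc$profile$counts, res$profile$counts)
  expect_equal(res_rc$profile$ic, res$profile$ic)
  expect_equal(res_rc$profile$consensus, res$profile$consensus)
})
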