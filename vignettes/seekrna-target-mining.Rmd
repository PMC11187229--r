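---
title: "Mining IS110/IS1111 target sites and analysing seekRNAs with isseek"
author: "isseek authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining IS110/IS1111 target sites and analysing seekRNAs with isseek}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isseek)
```

## The biology in brief

IS*110*- and IS*1111*-family insertion sequences are compact bacterial
mobile elements encoding a single DEDD (RuvC-fold) transposase. Unlike most
IS, each member selects a specific target sequence and inserts there in one
orientation, without duplicating the target. Three sequence features carry
the signal this package works with:

* a long **non-coding region (NCR)**, downstream of the transposase gene
  (*tnp*) in IS*1111*-type elements and upstream in the IS*110* type;
* for the IS*1111* family, **sub-terminal inverted repeats (sTIR)**, usually
  11–13 bp with a perfect or near-perfect match, set in from the element
  ends by short terminal extensions of 7 bp (left) and 3 bp (right),
  occasionally 6/3;
* a short NCR-derived **seekRNA** (~70–100 nt, with a longer ~150–170 nt
  precursor-like form) that co-purifies with the transposase and contains
  two short stretches complementary to the two strands of the target DNA.
  The 5'→3' order of the two stretches on the seekRNA — top-strand match
  first in IS*1111*, bottom-strand match first in IS*110* — is a family
  diagnostic.

Because excision regenerates an uninterrupted target when the flanks rejoin,
the sequences flanking every genomic IS copy record the element's
pre-insertion site, and stacking many such reconstructed sites reveals the
target consensus. That observation is the core of the mining pipeline; the
scanner, the peak caller and the reprogramming designer cover the
seekRNA-facing half of the analysis.

## The mining procedure

`run_target_pipeline()` chains five steps, each exposed separately:

1. **`filter_hits()`** applies the stringency filters used when collecting
   genomic copies from a nucleotide database search: E-value ≤ 0, percent
   identity ≥ `pident_min` (95 by default; 100 is the stricter published
   tier), query coverage = 100, and subject length within
   [`slen_min`, `slen_max`] = [10^5, 10^7] bp, which keeps assembled
   genomes and large replicons while discarding small or partial records.
   The hit format carries no strand column; `sstart > send` is interpreted
   as a minus-strand hit, the format's convention.
2. **`extract_flanks()`** takes the `flank_len` = 200 nt on each side of
   every hit. Minus-strand hits are reverse-complemented and the flanks
   swapped, so flanks are always in the element's own orientation — the
   only choice under which plus- and minus-strand copies of one element
   contribute the same columns to the logo (a property the tests assert as
   strand invariance). Hits closer than `flank_len` to a contig edge are
   skipped, not padded: padded columns would dilute real base counts with
   placeholder symbols.
3. **`reconstruct_sites()`** concatenates each flank pair into a
   2 × `flank_len` pre-insertion site with the insertion point exactly at
   the midpoint.
4. **`dedup_sites()`** collapses duplicates to unique insertion events. The
   primary rule is exact sequence identity (first occurrence kept); an
   optional `collapse_overlap` rule also merges sites whose IS intervals
   overlap on the same subject, for collections where near-identical
   flanks at one locus should count once. Both counts are reported, and the
   operation is idempotent.
5. **`build_consensus()`** stacks the sites positionally, anchored at the
   junction. No gapped multiple alignment is attempted: all sites are
   fixed-length and junction-anchored, so a gapped aligner can only perturb
   the columns; the cost is that insertion/deletion variation between sites
   is not modelled, which is acceptable for short linear targets and is
   stated here deliberately as a design decision. Per column the A/C/G/T
   counts (excluding N) give frequencies and the information content
   IC = 2 − *H* bits with *H* = −Σ *f* log₂ *f*.

### Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `pident_min` | 95 | % | published stringency tier; 100 available |
| `slen_min`, `slen_max` | 10^5, 10^7 | bp | genome-scale subjects only |
| `flank_len` | 200 | nt | flank window collected per side |
| `logo_halfwidth` | 20 | positions | logo width per side of the junction |
| `long_ncr` | 100 | nt | "long NCR" threshold (see below) |
| `ir_min`, `ir_mismatch` | 11, 1 | bp, count | sTIR length floor, mismatch budget |
| `ext_left`, `ext_right` | 7, 3 | bp | terminal extension constants |
| `ir_window` | 30 | nt | sub-terminal search window per side |
| `min_match_len` | 7 | nt | shortest reported seekRNA/target match |
| `alpha`, `long_alpha` | 0.5, 0.1 | fraction of max coverage | peak / long-form thresholds |

The small-sample correction e(n) = 3 / (2 ln2 · n) for the information
content is **off** by default so that a perfectly conserved column reads
exactly 2.0 bits; `ssc = TRUE` subtracts it. A column that is all-N has
undefined information content and is reported as `NA` with `.` in the
consensus string. Consensus letters whose majority frequency falls below
`consensus_min_freq` = 0.5 are lower-cased.

## Element annotation

`find_tnp_orf()` returns the longest stop-terminated open reading frame
across both strands and all frames, using bacterial start codons
(ATG/GTG/TTG). The floor `min_aa` = 250 sits safely below the 315–450 aa
range of these transposases while excluding spurious frames. The longest-ORF
rule is deliberate: detecting the DEDD motif itself would require a motif
model the annotation cannot justify from sequence alone, so motif-aware
selection is not attempted. Ties are broken toward the plus strand, then the
5'-most start; equally long overlapping ORFs on opposite strands attach an
ambiguity note.

NCR lengths are measured in the ORF's reading orientation (element start →
ORF start = upstream; ORF stop → element end = downstream), and an NCR
counts as "long" at ≥ 100 nt — the literature says "significant length"
without a number, so the threshold is exposed (`long_ncr`). The terminal
extension lengths are parameters (7/3), not detected: they are treated in
the field as family constants.

`find_stir()` searches a 30-nt window starting after the left extension and
ending before the right extension for the longest segment pair with
`left == revcomp(right)` up to `ir_mismatch` mismatches. Two numerical
choices: a repeat must begin and end with a paired base (otherwise, with a
mismatch budget of 1, every perfect repeat would be "extendable" by one
arbitrary base and lengths would be systematically inflated), and ties are
broken by fewest mismatches and then by the pair closest to the termini — a
mirror-symmetric criterion, so the same repeat is reported on an element and
on its reverse complement with mirrored coordinates.

`call_family()` combines the two lines of evidence: sTIR + downstream (or
both-sides) long NCR → IS1111-like; no sTIR + upstream (or both-sides) NCR
→ IS110-like; anything else is ambiguous, with the conflict listed (an sTIR
with an upstream NCR is the known ISMtsp17-like exception). A both-sides NCR
is allowed to support either family — the evidence that decides is then the
sTIR — because known elements with two long NCRs occur in both families.

## seekRNA scanning

`scan_seekrna()` enumerates **all maximal** segments of the seekRNA of
length ≥ `min_match_len` that pair antiparallel (Watson–Crick, in DNA
space; RNA input is canonicalised U→T) with the top or bottom strand of the
target, allowing `max_mismatch` mismatches (0 by default — the published
matches are clean, and the seekRNA pairs with DNA, so G:U wobble is not
modelled). Maximality means no reported match can be extended one base on
either side without exceeding the mismatch budget or running off an end; the
test suite asserts this against an exhaustive substring oracle. The default
`min_match_len` = 7 is a noise floor: on an ~80-nt RNA against a ~12-bp
target, shorter matches arise by chance too often to be informative, while
the figure-scale matches in this system are 7–10 nt.

Best match per strand = longest, then fewest mismatches, then 5'-most on
the seekRNA — an invented but deterministic tie-break (the original
analyses picked matches by inspection). The report records the 5'→3' order
of the two best matches (`T-before-B`, `B-before-T`, or `undetermined` when
a strand has no match or both start at the same position), whether the two
target footprints overlap, and whether the combined footprint straddles a
supplied insertion point. T and B matches may overlap on the seekRNA; they
are reported, not forbidden. `classify_family_by_order()` maps T-before-B
to the IS1111 pattern and the reverse to the IS110 pattern.

## Peak calling

`call_peak()` computes per-base coverage from read intervals (0-based
half-open, BED-like; read mapping itself is out of scope) and calls the
primary peak as the longest contiguous run with coverage ≥ `alpha` × max
(0.5), plus the longest run at `long_alpha` × max (0.1) as the long-form
candidate. The run-threshold rule is the package's own: the published
coverage figures show the two forms without stating a boundary rule, so the
thresholds are flags and the accuracy claim is made against simulator
ground truth (±3 nt on the peak, ±5 nt on the long form under the default
read-end jitter), not against the sequencing data.

## Reprogramming

`design_reprogram()` anchors the original best T and B match windows as
offsets from the insertion point, maps them onto the new target at the same
offsets, and writes the corresponding antiparallel complements into the
seekRNA at the original positions. The design is substitution-only — the
published reprogramming keeps the seekRNA architecture and swaps only
target-matching stretches — so length-changing designs are rejected rather
than attempted. If the T and B spans overlap on the seekRNA and the two
replacements disagree at any base, the design errors out
("inconsistent overlap edit"); nothing is resolved silently. The embedded
validation re-scans the designed seekRNA against the new target and flags
whether order and best-match lengths are preserved. Preservation can fail
for targets that by chance extend a rewritten segment into the unchanged
scaffold; the package reports this honestly rather than adjusting the
target, because choosing the target (including its strand — insertion is
orientation-specific, and the designer never flips it) is the user's
decision. Secondary-structure preservation is not verified: structure
prediction is outside this package's scope, and edited positions are simply
listed so they can be checked against a stem annotation if one exists.

`build_donor_layout()` emits the LF–LE–cargo–RE–RF donor annotation (LF/RF
= the new target split at the insertion point; LE/RE = outer element ends,
e.g. 50/46 bp for the IS*1111*-family mini-IS and 29/16 bp for the
IS*110*-family one), the predicted minicircle junction (RE abutted to LE,
the configuration that creates the junction promoter) and the reconstituted
target for primer design. An insertion point at either target end is
permitted but flagged degenerate.

## What the simulators emulate — and what they do not

`simulate_genomes()` states the mining world: uniform-composition background
contigs (configurable GC; no repeat families, no sequencing error), each
implant written as target-split-at-insertion-point with the IS between the
halves (no target duplication, so excision/rejoin restores the target
exactly — a property the tests assert), a stated fraction of loci on the
minus strand, exact positional duplicates realised as byte-identical locus
copies (flanking context included; duplicates inherit their source strand so
the copy really is positional), decoy target copies without an IS, and hit
rows formatted exactly as a search tool would emit them. Defaults are the
conditions used throughout the tests: 5 contigs ≥ 120 kb, 50 implants, 10
duplicates, 30% minus strand, the 12-bp target `GTGAAAATACTG` split at
position 6, 200-nt flanks. A green implant-and-recover test therefore
establishes that the pipeline's bookkeeping (coordinates, strand handling,
dedup, column counts) is exact; it says nothing about homology-search
sensitivity, taxonomic filtering, or mis-annotated element ends in real
catalogues, all of which are outside this package.

`simulate_seekrna()` plants the two complementary segments in random
scaffold in a requested order and rejects scaffold draws that would create a
spurious ≥ 7-nt match or extend a planted segment, so its ground-truth spans
are exactly what a correct scanner must report. `simulate_coverage()` draws
peak-form and long-form reads with up to `read_len_jitter` = 3 nt trimmed
independently per end; 150 peak reads over an 82-nt window inside 50 long
reads over a 154-nt window reproduce the published coverage shape at desk
scale.

All simulator draws derive from a single seed; identical configurations
produce byte-identical outputs.

## Numerical and interface conventions

Internal coordinates are 0-based half-open everywhere; adapters to the
1-based inclusive conventions of tabular hits and GenBank citations are
exact inverses, and BED I/O stays 0-based. Sequences live in DNA space with
an `is_rna` flag recording U→T canonicalisation, so seekRNA/target
complementarity is computed in one alphabet. Alphabet violations are
parse-time errors naming the record and position. The command-line wrapper
(`isseek_main()`; script in `inst/exec/`) exposes every threshold above as
a flag, writes all outputs under `--out`, and records a `manifest.json`
with the resolved configuration, input checksums and seed; exit codes are
0 (success), 1 (runtime/data error), 2 (usage error).

## Known limitations

* No gapped alignment of pre-insertion sites: length-variant targets
  (insertions/deletions between copies) will blur the logo.
* The NCR census thresholds used for published family-wide counts are not
  recoverable from the text, so those counts are not reproduction targets;
  `long_ncr` is a package choice.
* The ORF caller is longest-ORF, not motif-aware; a degenerate transposase
  or a longer overlapping ORF will mislead it (an ambiguity note is
  attached when detectable).
* Peak boundaries depend on the threshold flags; alternative rules (e.g.
  change-point detection) are not implemented.
* Phylogenetics, protein structure, RNA secondary-structure prediction and
  everything wet-lab are out of scope; the package emits sequences and
  annotated spans only.
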