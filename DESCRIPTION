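Package: isseek
Title: Target-Site Mining and seekRNA Analysis for IS110/IS1111 Insertion Sequences
Version: 0.2.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Toolkit for the analysis of bacterial insertion sequences of the
    IS110 and IS1111 families, which encode DEDD transposases guided to their
    targets by a short non-coding-region-derived RNA (the seekRNA). Provides
    genome mining of consensus target sites from tabular homology hits (flank
    extraction, pre-insertion site reconstruction, deduplication, per-position
    information-content profiles), annotation of IS elements (transposase ORF,
    non-coding region location, sub-terminal inverted repeats, family call),
    scanning of seekRNAs for target-complementary segments with the
    family-diagnostic match-order test, peak calling from small-RNA read
    coverage, programmable redesign of seekRNA and donor flanks for new
    targets, and seeded simulators that fabricate every input the toolkit
    consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
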