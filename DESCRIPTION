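Package: slcTE
Title: Transposable-Element Accumulation on Sex-Limited Chromosomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the accumulation of transposable elements (TEs) on
    sex-limited chromosomes (W in ZW systems, Y in XY systems). Computes the
    refugium index (excess TE-derived bp on a chromosome relative to the
    genome-wide average) and the toxicity index (excess of intact, potentially
    mobile TEs carried by the heterogametic diploid), divergence landscapes
    binned by Kimura 2-parameter distance to consensus, structure-based
    full-length ERV calls (paired LTRs, target-site duplications, internal
    gag/pol/env evidence) and homology-based full-length LINE/DNA-transposon
    calls, a chi-square test of uniform element density across chromosome
    classes, cohort-based discovery of female-specific (W-linked) SNVs in TE
    consensus space, and TPM-normalised per-chromosome TE expression
    summaries. A deterministic simulator generates genomes, repeat libraries,
    planted insertions and male/female read cohorts with a truth manifest so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite,
    withr
Config/testthat/edition: 3
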