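---
title: "Quantifying transposable-element accumulation on sex-limited chromosomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transposable-element accumulation on sex-limited chromosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slcTE)
```

## The problem

Sex-limited chromosomes (SLCs) — the W of female-heterogametic (ZW) systems
and the Y of male-heterogametic (XY) systems — do not recombine over most of
their length. Reduced recombination weakens selection against repeat
insertions, so SLCs accumulate transposable elements (TEs), and in birds the
W is dominated by endogenous retroviruses (ERVs). What matters functionally
is not the bulk repeat density but the number of *intact* (full-length,
potentially mobile) elements: a W packed with full-length ERVs exposes
females to a mutational load males do not carry. `slcTE` implements the
statistics and detection machinery needed to quantify this asymmetry in any
assembled genome with classified chromosomes.

## The two indexes

**Refugium index.** For a chromosome with observed TE density
$\%TE_{obs}$ (TE-derived bp over chromosome length, overlapping annotations
flattened first) and a genome-wide expected density $\%TE_{exp}$ (the
length-weighted mean over all included chromosomes of a haploid assembly),

$$RI = \frac{\%TE_{obs} - \%TE_{exp}}{\%TE_{exp}}.$$

$RI > 0$ is an excess, $RI < 0$ a depletion; by construction the
length-weighted mean of $RI$ over all included chromosomes is zero, which
the test suite checks as a conservation property. Unplaced scaffolds are
excluded by default; whether chromosome lengths should include assembly gaps
is genuinely ambiguous, so both modes are available
(`te_bp_by_chromosome(..., exclude_n = TRUE)` uses N-excluded lengths) with
gap-inclusive lengths as the default, matching how assembled chromosome
models are usually reported.

**Toxicity index.** With $n_{hom}$ and $n_{het}$ the total intact-TE counts
of the homogametic and heterogametic *diploid* genomes
($2A + 2Z$ vs $2A + Z + W$ in a ZW system, analogously for XY, $2A + X$ for
the heterogametic XO complement),

$$TI = \frac{2n_{het} - 2n_{hom}}{2n_{hom}}.$$

$TI = 0$ means no sex difference, $TI > 0$ toxicity of the W or Y,
$TI < 0$ toxicity of the Z or X. All intact-TE categories enter the totals
(fl-ERV plus full-length LINEs and DNA transposons): the bundled avian
worked examples (`avian_flte_counts()`) only reproduce their printed index
values to nine decimals under that reading, which settles the ambiguity in
favour of combined counts. Counts are integers, so the index is an exact
ratio; reports render it to nine decimals. The identity
$TI = (W - Z)/(2A + 2Z)$ and the lower bound $TI \ge -1/2$ at $W = 0$ are
checked as algebraic properties.

Three of the six bundled species have a female(2n) LINE+DNA cell that is
not consistent with their A/Z/W cells; the per-class and printed-total
routes to the index are therefore both implemented
(`avian_ti_worked_examples(from = ...)`), and the worked-example checks use
the printed male/female totals, plus the per-class route for the one fully
consistent species (zebra finch).

**Uniform-density test.** Observed per-class counts (A pooled, Z, W) are
compared to expectations proportional to class length with a chi-square
statistic on 2 degrees of freedom; at df = 2 the survival function is
exactly $e^{-X^2/2}$, which the tests use as a closed-form oracle against
`pchisq()`. Pooling autosomes is the default because the scientific
question contrasts chromosome classes; a per-chromosome variant
(df = number of chromosomes − 1) can be had by passing per-chromosome
observations directly to `uniformity_test()`.

## Divergence landscapes

TE age structure is summarised by binning each annotated copy's divergence
from its family consensus. Divergence is the Kimura 2-parameter distance

$$K = -\tfrac{1}{2}\ln\!\big((1 - 2P - Q)\sqrt{1 - 2Q}\big),$$

with $P$ and $Q$ the transition and transversion proportions over ungapped,
unambiguous alignment columns. Saturated pairs (non-positive logarithm
argument) are flagged undefined rather than silently zeroed. Plain K2P is
used — no CpG adjustment — because the landscape convention in the avian
repeat literature is the unadjusted estimator. Bins are left-closed
right-open (`[k·w, (k+1)·w)`, default width 1%), with everything at or
beyond 50% pooled into the last bin. Abundance is reported both as raw bp
and bp per Mb of chromosome-class length, since both normalisations are in
circulation. Divergence can come from the RepeatMasker annotation column or
be recomputed by global copy-to-consensus alignment
(`realign_divergence()`); both paths feed the same table schema.

## Full-length element detection

**Homology route (LINEs, DNA transposons).** Open reading frames are
maximal stop-to-stop stretches in all three frames — no start codon
required, because TE ORFs are routinely truncated at the 5' end by the
annotation rather than by biology. A LINE insertion is full-length when an
ORF of ≥ 600 bp spans ≥ 90% of both the endonuclease and reverse-
transcriptase domain consensi; a DNA transposon when an ORF of ≥ 1 kb spans
≥ 90% of the transposase. Domain span is measured by local alignment
(BLOSUM62, affine gaps) as aligned-consensus-residues over consensus
length. Whether EN and RT must sit on the *same* ORF is ambiguous in the
field's usual phrasing; the default accepts the two domains on different
ORFs of one insertion (`fulllength_criteria(same_orf = TRUE)` for the
strict reading), since CR1-type elements encode both domains on ORF2 but
annotation fragmentations often split the evidence.

**Structural route (fl-ERVs).** One unified paired-LTR detector stands in
for the two external tools usually run side by side; running it under two
`fulllength_criteria()` profiles reproduces the two-column census layout.
The algorithm: exact 11-mer seeding of same-strand direct repeats within
the structural window; two-stage clustering (chain seeds along the
sequence, then split chains by alignment diagonal, tolerating ±20 bp of
diagonal drift for indels); candidate LTR pairs must satisfy LTR length
100–1000 bp, element span 1.5–15 kb, and global-alignment LTR identity
≥ 0.80; a flanking 4–6 bp target-site duplication (TSD) is searched with
small boundary shifts and contributes to the score without being required.
Overlapping candidates resolve by identity then leftmost start. Internal
protein evidence is collected from ORF translations against gag/pol/env
consensi, and the composite score is

```
score = 100·LTR_identity + 25·TSD_present + 25·LTR_length_agreement
        + 150·(span_gag + span_pol + span_env)
```

with retention iff score ≥ 300 (`≥` semantics: a score exactly at the
threshold is kept) *and* at least one internal domain is at least "partly
complete" (span ≥ 0.5). The external tools' native score scales are not
portable, so the 300 threshold here is a calibration knob chosen so that an
intact element with identical LTRs, a TSD and all three genes scores 600,
an element with a single complete gene sits exactly at the threshold, and a
bare LTR pair with random internal sequence scores ≈ 160 and is rejected
twice over (score and domain gates). A `pol` span ≥ 0.5 additionally flags
the call "likely autonomous". Domain evidence can also be ingested from a
precomputed RPS-BLAST-style hit table (`read_domain_hits()`).

**Boundary determinacy.** With exact seeding, a detected LTR boundary can
over-run by a few bp when a flanking base coincides with the LTR edge; the
TSD-anchored refinement then has two genuinely valid readings of the
sequence. The refinement prefers the longer TSD and breaks ties toward the
smaller shift, and recovery comparisons in the tests allow ±3 bp. On
constructed fixtures with pinned junction bases the coordinates are exact.

## W-linked SNV discovery

Reads from male and female cohorts are aligned to the TE consensus library
and piled up per (family, position, allele) with CIGAR-aware placement,
primary/non-duplicate filtering and mapping/base-quality floors. Presence
gates (package defaults, all configurable because the upstream pipelines
never print theirs): a site/allele is *present* in a sample iff depth ≥ 5,
alt count ≥ 3 and alt frequency ≥ 0.20; *absent* iff depth ≥ 5 and alt
frequency ≤ 0.05; otherwise *indeterminate*. A variant is **W-linked** iff
present in every female genomic sample and absent in every male genomic
sample; an indeterminate call anywhere excludes the site. Requiring
adequate male coverage for "absent" (rather than counting missing coverage
as absence) is the conservative reading and is deliberate: a W-linked call
should never rest on a male sample that simply was not sequenced deep
enough. Cohorts with a single male are accepted with a warning, since
single-male designs are known to inflate false positives. W-linked variants
present in ≥ 1 female RNA sample are flagged transcribed; any presence in
male RNA discards the variant as a false positive. Multi-allelic sites are
handled per alternate allele; indels are out of scope.

The bundled `naive_map()` (exact-seed, ungapped, best-unique-hit) exists so
the whole cohort path is testable without an external aligner; real data
should be mapped externally and fed in as SAM text.

## Expression summaries

Per-copy counts are TPM-normalised
($TPM_i = (c_i/\ell_i)/\sum_j (c_j/\ell_j) \cdot 10^6$; each sample sums to
$10^6$, a conservation law the tests assert). Male-sample rows on the W are
removed *before* normalisation — males carry no W, so those counts are
mapping noise that would otherwise deflate the other classes. Replicates
are averaged per sex, values grouped by chromosome class, and classes
compared with a two-sided rank-sum test: exact enumeration of all group
assignments up to combined n = 20 (ties handled by permutation),
tie-corrected normal approximation beyond. The accompanying log2 ratio of
mean TPM is a descriptive contrast only — no dispersion modelling or
shrinkage is attempted, and the output labels it accordingly.

## The simulator and what passing tests mean

`simulation_config()` defaults are the study conditions of the test suite:
a ~2.1 Mb ZW genome (two 500 kb autosomes, 400 kb Z, 700 kb W), 32 planted
full-length ERVs split (10, 2, 20) across A/Z/W, 20 solo-LTRs, 20
internal-only fragments, error-free copies, with 16 kb spacing between
insertions (above the 15 kb maximum element span, so no cross-element seed
pairing can form a valid candidate and the truth manifest stays
unambiguous). Planted full-length elements carry both LTRs, a TSD and
intact gag/pol/env ORFs built from fixed-codon back-translation of random
domain peptides; solo-LTRs are one LTR plus TSD (the recombination relic);
fragments lack LTRs and domains. The W is the largest chromosome here
purely to hold its 30 insertions at full spacing — 2 Mb overall keeps the
detector run near half a minute.

Copies are mutated to a target K2P distance by drawing per-site transitions
and transversions with probabilities obtained by inverting the K2P
expectations at rate ratio $\kappa = \alpha/\beta$ (default 2); this hits
the target in expectation, with binomial scatter of roughly ±0.01 at
K = 0.10 on 5 kb elements (the tests allow [0.08, 0.12]). The annotation
rows carry the *realized* divergence of each copy.

Read cohorts (3 female + 3 male genomic samples, 30× coverage, 100 bp
error-free reads by default) are drawn from compact TE-copy haplotypes —
per family, two autosomal copies in everyone plus two W-linked copies in
females — because background sequence never reaches consensus-space
pileups; this keeps full-cohort mapping under a minute without changing
what is being tested. W-restricted variants sit on the W copies only
(female alt frequency ≈ 0.5, male 0), autosomal variants on the autosomal
copies of every sample. Variants are planted ≥ 150 bp from copy ends so
that edge-depth effects (reads overhanging a copy cannot map) do not touch
them. RNA samples draw reads only from copies of "transcribed" families.

What the simulator does *not* emulate: nested insertions, sequencing
error profiles, indels in reads, paired-end structure, real repeat-family
phylogenies, CpG hypermutability, or assembly gaps. Passing recovery tests
therefore demonstrate correctness of the detection and calling logic under
clean conditions — not performance on degraded real-world assemblies,
where boundary accuracy and recall will be lower.

Determinism: one root seed feeds fixed-offset substreams per output, so
adding an output stream never perturbs existing draws; all outputs are
byte-identical under a fixed seed.

## Numerical and degenerate-input conventions

Internal coordinates are 0-based half-open everywhere; conversion happens
only at format boundaries (RepeatMasker `.out` and GFF3 are 1-based
inclusive, BED is 0-based half-open). K2P saturation yields a flagged NA.
`refugium_index()` refuses $\%TE_{exp} = 0$, `toxicity_index()` refuses
$n_{hom} = 0$, `uniformity_test()` refuses empty observations or zero
expected cells. Empty annotations produce empty (not missing) tables.
Rank-sum ties: exact path enumerates permutations, approximate path applies
the standard tie correction without continuity correction. Detector ties
break deterministically (score/identity, then leftmost).

## Scope notes

The census layout mirrors intact-TE tables for six avian reference
assemblies bundled as worked examples; reproducing those species' absolute
counts, landscapes or expression panels requires the real assemblies,
repeat libraries and sequencing cohorts and is outside the test suite's
reach — the planted-truth property suites stand in for them. Repeat-library
curation, read trimming/mapping at scale, dispersion-modelled differential
expression and proteomics are likewise out of scope.
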