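---
title: "Methods: circRNA expression heterosis analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circRNA expression heterosis analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circheterosis)
```

# The analysis

`circheterosis` analyses circular RNA (circRNA) expression in a classic
heterosis design: a female parent (FP), a male parent (MP), and F1 hybrids
that differ in growth potential (here three high-growth and two low-growth F1
genotypes, three biological replicates each, 21 samples in total). The
questions it answers are those a hybrid-breeding transcriptomics study asks
of circRNAs:

1. Which back-splice junctions are reproducibly supported by two independent
   callers, and where do the resulting circRNAs come from in the genome?
2. How is each circRNA inherited — additively (F1 expression at the
   mid-parent value) or non-additively, and in which Stupar subtype
   (above-high-parent, high-parent, low-parent, below-low-parent)?
3. Which circRNAs are single-parent expressed (SPE), co-expressed by both
   parents (CoPE), or specific to the F1s (SFE)?
4. Could the circRNAs act through miRNA sponging or through cap-independent
   translation of a circular open reading frame (ORF)?
5. How does circRNA expression co-vary with parent genes and with
   genome-wide co-expression modules tied to the growth phenotype?

Every stage is driven by plain matrices and data frames, so real caller
tables, annotations and count matrices can be substituted for the synthetic
ones at any point.

# Catalog construction

Two caller tables (chrom, start, end, strand, back-spliced reads, sample)
are merged by `merge_calls()`. Calls group when chromosome and strand match
and *both* the start and end coordinates differ by at most 10 nt (the
conventional tolerance for back-splice breakpoint wobble between CIRI-style
and find_circ-style callers); the window is inclusive, so a 10-nt offset
merges and an 11-nt offset does not. Grouping is single-link, so chains
collapse into one entry. The representative coordinates are those of the
call with the highest total read support, with ties broken toward caller A
and then the smaller start — the provenance of every entry is retained via
`n_callers` and `support`. Per sample, the merged count is the mean of the
two callers' counts when both report, and the single caller's count
otherwise; halving a junction seen by only one caller would penalise
caller-specific sensitivity.

`classify_origin()` intersects each circRNA span with the gene annotation:
`exonic` needs both back-splice ends inside exons of one containing gene,
`intronic` needs the whole span inside a single intron, any other
gene-overlapping span is `exon_intron`, and spans overlapping no gene are
`intergenic`. Overlap is evaluated on the matching strand first; if no
same-strand gene overlaps, either strand is accepted and the call is flagged
`strand_rescued`, which prevents antisense-derived circRNAs from being
misfiled as intergenic.

# Quantification and inheritance classes

Expression is back-spliced reads per million mapped reads (RPM):
`counts * 1e6 / mapped_reads` per sample. Expression bins are `low`
(< 100 RPM), `moderate` (100–500 RPM, both boundaries inclusive) and `high`
(> 500 RPM). Genotype means are arithmetic means over replicates, and the
mid-parent value is `MPV = (mean_FP + mean_MP) / 2`.

Differential expression follows the two-pooled-library paradigm: replicates
are pooled within each group and, conditional on a feature's total count,
the group-A count is binomial with null proportion equal to group A's share
of the pooled library sizes. The two-sided p-value doubles the smaller tail,
capped at 1. This exact conditional test is fully reproducible and needs no
dispersion estimation; the deliberate trade-off is that replicate-level
biological variance is not modelled (a DESeq2-style NB GLM is out of scope
because the design under study fixes the two-library paradigm). The log2
fold change compares pooled rates with a pseudo-rate
`eps = 0.5 / min(n_a, n_b)` so single-group zeros stay finite. Benjamini–
Hochberg adjustment produces q-values, and a feature is a differentially
expressed circRNA (DEC) when `|log2FC| >= 1` and `q <= 0.05`, both
inclusive.

A circRNA is **non-additively** expressed in an F1 when its F1-vs-MPV
comparison is a DEC; the MPV pseudo-library pools the two parents' counts
and library sizes, keeping the test count-based instead of inventing a count
for an averaged RPM. Non-additive calls are subtyped by `classify_stupar()`:
significantly above the MPV and above the high parent is AHP, otherwise HP;
significantly below the MPV and below the low parent is BLP, otherwise LP.
The high and low parents are fixed as the female and male parent by growth
potential — not by expression level — because that is how the breeding
design defines them; `stupar_by_expression = TRUE` restores the
higher-expressing-parent convention for users who want it.

The parental taxonomy is presence/absence: SPE-F circRNAs are detected in
the female but not the male parent, SPE-M the reverse, CoPE in both, and SFE
in neither parent but at least one F1. Presence defaults to the
any-replicate rule, because single-parent expression is defined by absolute
absence in one parent — which the merged counts express as structural
zeros — and a mean-positive rule is equivalent for non-negative data (both
are available).

One printed-arithmetic subtlety: with both parents expressed, an F1 at or
below the high parent can never be twofold above the MPV (2·MPV ≥ the high
parent mean always), so HP calls are confined to boundary cases where the
low parent is silent. Field studies accordingly observe HP rates near zero;
the synthetic generator's default class mix plants none, while
`classify_stupar()` handles the case whenever the thresholds admit it.

# Function prediction

miRNA target sites are scored with the plant penalty scheme: aligned
antiparallel and gap-free, each position contributes 0 for a Watson–Crick
pair, 0.5 for a G:U wobble and 1 for a mismatch, doubled at miRNA positions
2–13 from the 5' end; sites at or below penalty 4.0 are reported (the
conventional cutoff for plant target finders). Because the molecule is
circular, the first miRNA-length-minus-one nucleotides are appended before
scanning, so junction-spanning sites are found; scores are invariant to
rotating the circle.

Circular ORFs are found by scanning all three frames of the sequence
concatenated four times; an ORF runs from ATG to the first in-frame stop,
its length counted start through stop codon inclusive, with starts mapped
back to the first copy so wrap duplicates collapse. ORFs crossing the copy
boundary are flagged `spans_junction`; a frame whose ATG never reaches a
stop within the allowed wraps is flagged `rolling` (rolling-circle
translation) with its length truncated to frame. The reporting floor is
63 nt — a start codon, 19 internal codons and a stop — matching the shortest
product such studies report. Four wraps bound the rolling case; the exact
wrap count only affects the reported length of rolling ORFs, never whether a
stop-terminated ORF is found. Coding potential is the conjunction of an ORF
and an IRES: IRES prediction requires a trained sequence model, so the
pipeline consumes an optional boolean IRES annotation and otherwise labels
its output ORF-only.

# Correlation and co-expression

Each circRNA's RPM profile is Pearson-correlated with its parent gene's
FPKM profile across all samples, with the exact t-transform p-value
(`p <= 0.05`, unadjusted, as is conventional for this screening step; BH
adjustment is available). Zero-variance profiles yield NA and leave the
summaries. Exact r = 0 ties count as positive — a measure-zero event kept
deterministic.

Co-expression follows the WGCNA recipe on the combined differential
feature matrix: unsigned adjacency `|cor|^beta` with the smallest power
whose scale-free fit reaches R² ≥ 0.8 (fallback 6), the standard
topological overlap matrix, average-linkage clustering of `1 − TOM` with a
static cut at height 0.99 (a static cut is deterministic and sufficient for
planted-block recovery; dynamic tree cutting is deliberately out of scope),
modules smaller than 5 features dropped to grey, and size-ordered WGCNA
color labels. Eigengenes are first singular vectors of the standardized
module submatrix, sign-oriented so the mean correlation with module members
is positive — a deterministic orientation. Module–trait correlation uses
binary genotype (or role-group) indicators; hubs are the top-k features by
intramodular connectivity `kWithin`, the standard surrogate for
network-viewer hub picking. Term enrichment is the upper-tail
hypergeometric test (`phyper`), thresholded at p ≤ 0.05.

# The synthetic study and what it does (not) show

`simulate_study()` plants every label downstream stages must recover, at
the design such crosses use: 7 genotypes × 3 replicates, with
per-sample mapped-read totals drawn uniformly from 1–10 million at toy
scale (real libraries are ~100× deeper; totals only exercise RPM
normalization, so scale is immaterial). Defaults: 40 genes on 2
chromosomes, 150 circRNAs mixed 57.2 / 40.2 / 1.0 / 1.6% over
intergenic / exonic / intronic / exon_intron (the proportions typical of a
leaf catalog), lengths mainly 100–700 nt, 20 miRNAs of 20–22 nt.

Key generator guarantees, each covered by tests:

* **Re-classification fidelity.** Every planted circRNA re-classifies to its
  planted origin; exonic sequences are spliced exon concatenations,
  intronic/exon_intron/intergenic are contiguous genomic subsequences
  (reverse-complemented on the minus strand). The genomic-vs-spliced
  convention for the mixed classes is a package choice; callers disagree
  and the source studies do not state one.
* **Identifiability.** Planted circles are placed so that no two lie within
  the merge window of each other even after maximal caller jitter (ends
  clamped to ±5 nt), so a noise-free run reproduces the catalog exactly and
  a jittered run still matches one-to-one.
* **Class semantics.** Heterosis classes are drawn once per growth group
  (high/low) per circRNA — parents are shared across F1s, so class-specific
  parent constraints (LP needs FP ≥ ~3× MP to leave room between MPV/2 and
  MP) can only be enforced at the circRNA level — and planted means provably
  satisfy each class definition. Counts are negative binomial
  (Gamma–Poisson, dispersion 0.05 by default, Poisson at 0): the standard
  overdispersion model for RNA counts, since the design itself specifies no
  noise model. SPE/SFE zeros are structural — exact zeros, not small means —
  because single-parent expression is defined by absence.
* **Function truth.** Planted miRNAs are reverse complements of windows of
  already-extracted circRNA sequences (possibly spanning the junction), so
  each planted site scores exactly 0 without editing any sequence. Planted
  ORFs are written into the genome before extraction, on intergenic
  plus-strand circles, over a C/G-only background in which neither a start
  nor a stop codon can arise by chance — the planted junction-spanning ORF
  is therefore the circle's only ORF.
* **Coupled parent genes.** Each parent gene's FPKM profile tracks its
  circRNA's realized RPM with a planted sign (positive for SPE-F hosts,
  negative for SPE-M hosts, random otherwise), offset to stay positive so
  clipping cannot distort the planted correlation.

What passing these tests does **not** show about real data: the generator
draws independent features (no shared transcriptional programs beyond the
planted ones), jitter and dropout are the only caller artifacts (no
strand-flips, no chimeric calls), library composition effects are absent
(RPM is taken at face value), and the miRNA background is uniform random
sequence rather than a real miRNome. Results on real data will additionally
depend on annotation quality and caller-specific biases that the emulation
does not model.

# Numerical and policy choices

* Coordinates are 1-based inclusive throughout (GFF convention); caller
  tables in other conventions must be converted at ingest (negative lengths
  are caught as a convention error).
* Merged counts can be half-integers (two-caller averages); the exact
  binomial test rounds pooled counts to the nearest integer at entry.
* Expression-bin boundaries 100 and 500 RPM are `moderate`; DEC thresholds
  are inclusive at exactly `|log2FC| = 1` and `q = 0.05`.
* Features with zero counts in both groups of a comparison are excluded
  (NA), as the conditional test is undefined there.
* The additivity test set per F1 genotype is features expressed in that F1
  or with MPV > 0.
* Problem sizes in the test-suite: the default simulated study uses 150
  circRNAs (2000 for the origin-proportion convergence check), 2000-feature
  null simulations for calibration, and 20-feature instances for
  element-wise TOM verification — sizes at which every check runs in
  seconds while the sampling tolerances stated in the tests remain sharp.

# Limitations

The exact binomial test inherits the two-library paradigm's blind spot for
replicate variance; its q-values are well calibrated under the pooled null
(verified by simulation) but anti-conservative if biological replicates are
strongly overdispersed. The static tree cut will split or lump modules that
a dynamic cut separates on real, continuously structured data. IRES
prediction is consumed, not performed. GO/KEGG enrichment operates on
whatever term assignments are supplied; the package ships no ontology.
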