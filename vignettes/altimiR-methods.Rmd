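---
title: "Methods: small RNA profiling across altitudinal plant populations"
author: "altimiR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA profiling across altitudinal plant populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(altimiR)
```

## The analysis problem

Natural plant populations sampled along an altitudinal gradient experience
very different temperature and radiation regimes over short geographic
distances. Comparing the miRNA complement of such populations — in the field
and in a common glasshouse garden — asks several linked questions: which
miRNAs are expressed where, which change with altitude, how the two arms
(5p/3p) of each hairpin are used, how the isomiR spectrum of each miRNA is
composed, whether unannotated hairpins produce genuine miRNAs, and how
expression tracks multivariate climate. altimiR implements this analysis as
a set of composable stages over Bioconductor containers, together with a
fully seeded synthetic-data generator so every stage can be exercised with
known ground truth and no external downloads.

## Read processing and hierarchical classification

Raw single-end reads are adapter-trimmed (leftmost match of the adapter's
first 8 bases, at most 1 mismatch — the seed length and tolerance are
configurable), filtered at mean Phred >= 20 (the threshold is a convention;
"low quality" has no unique definition), size-selected to 18–28 nt, and
collapsed to unique tags with per-library counts. Classification is
sequential and first-match-wins: tags absent from the genome are set aside;
genome-mapped tags are tested against cDNA, t/rRNA, sno/snRNA and tasiRNA
pools in that fixed order and discarded on the first hit; surviving "clean"
tags equal to an annotated mature sequence become miRNA counts; the rest
feed novel-locus discovery. Matching is ungapped exact substring search —
both genome strands, sense-strand pools — with a configurable substitution
allowance for the mature comparison (default 0). Exact matching is the
conservative default for collapsed small RNA tags; the order-dependence of
the pool cascade is deliberate and tested.

Identical mature sequences annotated at several loci are collapsed into one
expression unit whose counts are never double-assigned; multi-locus
ambiguity cannot be resolved by short reads, and per-family reporting does
not require it.

## Quantification and differential expression

Counts are normalized to reads per million. The denominator is the
per-library cleaned-read total (genome-mapped minus contaminants) by
default, switchable to the miRNA-mapped total — the two options bracket the
common conventions. Cells with a zero raw count are set to exactly 0.01 RPM
after normalization so every log2 fold change is defined. A unit counts as
detected in a scope of libraries when its pooled raw count reaches 10.

Pairwise differential expression uses the Pearson chi-square statistic on
the 2x2 table of unit count vs remaining reads in the two libraries, with no
continuity correction (a Yates flag exists) and no multiple-testing
correction by default (Benjamini–Hochberg is available). A comparison is
only flagged `tested` when the count exceeds 10 in at least one library.
The default "significant" gate is tested AND p < 0.05 AND |log2FC| >= 1;
all three thresholds are configuration keys, and the monotone-with-altitude
sets (significant in the same direction in both the low-to-mid and
mid-to-high steps) inherit this gate. Between-library similarity uses
presence/absence Jaccard with a seeded percentile bootstrap that resamples
the union universe jointly — the joint scheme keeps the degenerate cases
exact (identical sets give CI [1,1], disjoint sets [0,0]), which per-set
resampling cannot. Library clustering uses average linkage on
1 − Pearson r over log2 RPM profiles, and the population x condition ANOVA
fits `log2(rpm) ~ population * condition` with type-II sums of squares
(log2 stabilizes the multiplicative scale of RPM values).

## The seven-class isomiR taxonomy

Each tag is classified against a mature located on its hairpin by a
first-match decision tree: canonical (exact sequence); templated variants
found as exact hairpin substrings with both end offsets within a window
(default 5 nt) — shifted (both offsets equal), 3' template
(addition/deletion at the 3' end only), start-site (5' end only), both-end;
non-templated 3' additions (longest templated prefix plus a 1–5 nt tail
whose first base differs from the template continuation), with either
canonical or shifted 5' start; and internal substitutions (1–2 mismatches,
never at the first or last position). Overlaps are resolved by precedence:
a length-preserving tag whose final base mismatches the template is a 3'
NTA, not a substitution, reflecting the biology of nucleotidyl-transferase
tailing. The tail-length bound is a constant (`maxTail`, default 5) kept
separate from the offset `window`, so enlarging the window can only rescue
unassigned tags, never re-categorize assigned ones. Tags classifiable
against several matures go to the one with the smallest total end offset,
ties to the 5p arm. The test suite checks the classifier against an
independently coded brute-force oracle on exhaustive tag enumerations.

Per-miRNA summaries report category proportions, distinct isomiR counts and
diversity as dominance — the most abundant single isomiR sequence over the
miRNA total (scale-invariant). NTA base composition is read-weighted over
the first tail base on the RNA alphabet. Arm usage compares raw canonical
counts of the 5p and 3p matures of one hairpin; zero counts enter the log2
ratio via the 0.01-RPM convention and significance is a two-sided exact
binomial test against 0.5 (the choice of test is ours; only "p < 0.05" is
conventionally reported for arm bias).

## Novel hairpin validation

Clean unassigned tags with pooled counts >= 10 are mapped to the genome
(tags with more than 20 loci are discarded as repeat-derived), overlapping
hits merged into loci led by the most abundant tag, and a window of the tag
plus 100 nt per side emitted in both orientations. Folding is an injected
engine contract — any function returning a minimum-free-energy dot-bracket;
production wiring uses ViennaRNA's `RNAfold` when present, and the test
suite uses deterministic stubs. Validation implements three duplex
criteria: (a) mature and star on opposite stem arms forming a duplex with
the canonical 2-nt 3' overhangs (the star span is the partner interval of
the mature shifted by 2; self-pairing matures, e.g. spanning the terminal
loop, fail); (b) at most 4 unpaired mature positions; (c) at most one
asymmetric bulge, none larger than 2 nt. Failure reasons are enumerated per
clause so spoiler constructions fail for exactly the intended reason.
Genomic origin is labeled exonic on any exon overlap, else intronic inside
a gene, else intergenic.

## Climate association

The site-by-variable table (19 bioclim variables plus growing-season AT,
AP, AR) is standardized — obligatory with mixed units — and decomposed by
correlation-matrix PCA; component signs are fixed so the largest-magnitude
loading is positive. With three sites exactly two components carry all
variance. Expression (libraries averaged within site) is Pearson-correlated
with component scores and with the growing-season factors. Correlation
flags require |r| above a threshold (default 0.98) and p below alpha; with
three sites such p-values are severely underpowered (|r| > 0.997 is needed
for p < 0.05), so results carry a low-power flag and an alternative literal
reading (p > alpha) is available as a configuration switch for
compatibility with reports that used it.

## The synthetic study generator

The generator emulates the study design rather than any particular dataset:
three populations (low/mid/high altitude) sampled in the field in two
years, the same populations in a glasshouse, plus one reference-accession
control — ten libraries of 1e5 reads each by default. That desk-scale depth
(real studies reach several million cleaned reads per library) keeps the
full pipeline run within a couple of minutes; all recovery tolerances were
chosen for this scale. Hairpins are perfect inverted repeats (27-bp stem,
8-nt loop, 12-nt unpaired 3' flank) embedded sparsely in a random genome, so
every mature is an exact genome substring, every precursor is foldable by
construction, and genome fragments overlapping a mature remain fully
templated. Arm-annotation classes mirror observed frequencies (half
"no arm", about a third "both arms"); one mature sequence is planted at two
loci to exercise unit collapsing. Abundances are log-normal per hairpin
(sdlog 0.8); planted monotone-altitude units carry 1/3/9 population
multipliers at a pinned moderate abundance, so their fold changes stay well
above the significance gate after compositional renormalization;
condition-responsive hairpins carry glasshouse multipliers of 4 or 0.25;
two units are exclusive to the high-altitude population and one to the
mid-altitude one. IsomiR categories follow a fixed mixture (72% canonical,
10% NTA, 8% 3' template, 5% both-end, 3% shifted, 1% each substitution and
start-site — within the ranges typically reported for plant leaf
libraries); NTA tail bases are drawn from weights with zero guanosine, the
construction pinning every template continuation to G so the NTA/template
distinction is unambiguous; substitutions are planted centrally (positions
5–15), as terminal-region mismatches are by definition tail-like under the
taxonomy's precedence. Contaminant fragments (20% of reads), background
genome fragments with condition-specific length modes (21 nt field-like,
24 nt glasshouse-like), reads from two unannotated hairpins (one intronic,
one intergenic), low-quality reads and adapter-only reads complete each
library. The manifest records the design, per-library true unit
proportions, multipliers, arm shares, realized category counts and tail
bases — everything recovery tests need.

What the generator does not emulate: sequencing error beyond planted
substitutions, quality-score structure, RNA-modification artifacts, mapping
ambiguity from repeat families, or biological replicate variance beyond
multinomial sampling. Passing recovery tests therefore demonstrates the
correctness of the computations, not robustness to every artifact of real
libraries.

## Numerical and design choices

* Coordinates are 1-based closed intervals throughout (the Biostrings and
  IRanges idiom), including the annotation TSV.
* The chi-square statistic is computed in closed form in double precision;
  degenerate tables (empty margins) return statistic 0, p 1.
* ANOVA on a unit with identical responses returns p = 1 by convention;
  designs with an empty cell drop the interaction with a warning.
* Dendrogram leaf order is made deterministic by sorting libraries by id
  before clustering; zero-variance profiles are an error naming the
  library.
* PCA components with variance below 1e-10 of the leading eigenvalue are
  treated as numerically null; constant variables are dropped with a
  warning.
* All stochastic stages (bootstrap, generator) take explicit seeds and
  restore the caller's RNG state.

## Limitations

Exact-match classification undercounts miRNAs whose dominant form is an
isomiR; the isomiR module quantifies those separately rather than folding
them into the expression matrix. The 0.01-RPM zero rule makes fold changes
from absent units depend on library depth. Three-site climate correlations
are descriptive, not inferential. Hairpin validation checks duplex
geometry only; it does not compute folding p-values or conservation, and a
rare random locus can pass the structural screen — verdicts are a filter,
not proof of miRNA biogenesis.
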