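---
title: "Methods: mitogenome reorganization, codon usage and divergence"
author: "mitoRearr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitogenome reorganization, codon usage and divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoRearr)
```

# Scope and data model

`mitoRearr` analyses the reorganization of circular mitochondrial
genomes: it classifies gene orders against the vertebrate ancestral
arrangement, reconstructs tandem duplication–random loss (TDRL)
rearrangement scenarios, quantifies codon usage (RSCU) under the
vertebrate mitochondrial code, tests whether codon usage tracks each
tRNA gene's distance from the control region (CR), and estimates
pairwise synonymous/nonsynonymous divergence. The package was designed
around the rearrangement biology of anuran mitogenomes — the
neobatrachian *LTPF* cluster, the WANCY rearrangement hotspot,
pseudogene relics such as ψtrnS(AGY), tRNA losses and CR/trnM
duplications — but nothing restricts it to frogs.

Genomes are `MitoGenome` objects: id, length, circular flag, optional
sequence, and an ordered feature table with MitoZoa-style tokens
(`cox1`, `nad5`, `trnL(CUN)`, `rrnS`, `CR`, `OL`, ...). Coordinates
are **0-based half-open on the circle**; a feature may wrap the
numbering origin (represented by `start > end`, end taken modulo the
length). GenBank's 1-based inclusive locations (including
`join(x..L,1..y)` wraps) are converted on read/write. This convention
was chosen because every downstream quantity (feature length, spacer
gaps, tRNA–CR distances) is then a single modular subtraction, with no
±1 case analysis.

Gene nomenclature is normalized through a versioned table shipped with
the package (`inst/extdata/gene_name_map.tsv`) plus rules for
`tRNA-Xxx` products; Leu and Ser isotypes are resolved by a
`(UUR)/(CUN)/(AGY)/(UCN)` suffix or by the anticodon, and an
unresolvable Leu/Ser is assigned the more common isotype with a
warning rather than dropped. Unknown names are kept as `noncoding`
features with a warning — silently dropping annotation would corrupt
gene-order extraction.

# Gene orders and classification

A `GeneOrder` is a circular sequence of tokens (name, strand,
pseudogene flag). Equality is rotation-invariant; copy indices are
ignored in comparisons because they depend on the arbitrary
linearization point. For display and tables, orders are linearized at
the token following the CR 3' end, the natural biological origin
(heavy-strand transcription leaves the CR).

`extractGeneOrder()` omits annotated noncoding features and
unannotated gaps shorter than `spacerMin` (default 30 bp) and emits
explicit `spacer` tokens for longer ones. The default is small enough
to report genuine intergenic spacers (e.g. the 300–500 bp
nad5–nad6 spacers seen in some ranids) while ignoring the few-bp
joints ordinary annotation leaves between genes.

`classifyOrder()` labels an order `AGO` only if its functional tokens
are rotation-equal to the vertebrate reference *and* it carries no
pseudogenes, duplications or losses; everything else is `RGO` with
named diagnostics (`LTPF_cluster`, `WANCY_intact`,
`trnH_translocated`, `trnM_duplicated`, per-gene losses and
duplications, pseudogene list). Pseudogenes are excluded from
order-equality and from adjacency distance but retained as
diagnostics: a genome that is "typical except for a pseudogene" should
compare as typical. A gene reduced to a pseudogene relic is reported
under `pseudogenes`, not under `lost` — losses are reserved for genes
with no remaining trace. Strand is part of token identity in the
shared-adjacency distance, so a hypothetical inversion breaks
adjacencies even though no inversions occur in the motivating taxa.

# TDRL scenario inference

A single TDRL event duplicates a contiguous tract in tandem and then
silences redundant copies: for every gene in the tract exactly one
copy is retained, the other is pseudogenized (leaves a flagged token)
or deleted (leaves nothing). `inferTDRL()` searches all duplication
intervals and, for each, all ways of splitting the observed mid-region
into a left-copy and right-copy subsequence; because gene names within
the ancestral tract are unique (a documented precondition), the fate
table for a given interval and split is determined, so the search is
polynomial rather than exponential. All scenarios of minimal cost are
returned, with cost compared lexicographically — fewest duplicated
genes, then fewest non-retained copies — and ties reported rather than
broken silently.

Design notes:

* A derived segment identical to the ancestral one returns an empty
  list ("no event needed"), distinct from an unexplainable segment
  (also empty) and from an inconsistent one (a gene name absent from
  the ancestor: an error).
* Only single events are searched; multi-event histories are declared
  unexplained. Composition can be layered on top
  (`applyRandomTDRL()` does exactly that in simulation).
* Partial duplication of boundary genes (known from sequence-level
  evidence in real WANCY rearrangements) is not modelled at the order
  level; a boundary pseudogene may descend from a partial copy. As a
  consequence the minimal gene-level interval can be one gene shorter
  at each boundary than the tract a sequence alignment would draw:
  for the *Amolops*-type order `W A' N' OL A N OL' C Y` the minimal
  scenario duplicates `trnA–trnN–OL` (cost 3,3), where sequence
  evidence suggests a physical tract reaching into trnC. Both explain
  the observed order; the package reports the parsimonious one.

Correctness is checked two ways: every returned scenario must
reproduce the derived segment through the forward model
(`applyTDRL()`), and on all segments of up to six genes the returned
set is compared exhaustively against a brute-force enumerator of every
interval × fate assignment (5,436 distinct derivations).

# Codon usage, RSCU and the tRNA map

Codons are counted per gene, in that gene's own frame and strand
(reverse complement for minus-strand genes), under the vertebrate
mitochondrial code (NCBI table 2: AGA/AGG stop, ATA Met, TGA Trp).
Terminal stop codons and incomplete terminal codons are excluded;
codons with ambiguity characters are skipped and tallied; an internal
stop warns and flags the gene (pseudogene suspicion) without aborting
the genome. Physically overlapping genes (atp8/atp6 style) contribute
their shared nucleotides to both genes' tables — "considered once
*for each gene*" — matching how standard codon-usage tools enumerate
genes independently; a `overlapOnce` switch implements the alternative
reading (shared codons counted only for the first gene). Alternative
initiation codons are counted as their literal codon: recoding them to
Met would require knowing which tRNA reads them, which the data do not
say.

RSCU for codon *c* in family *F* of size *n* is
`x_c / ((1/n) * sum(x_F)`). Families are the synonymous families of
the code with **Leu split into CUN/UUR and Ser into AGY/UCN** — each
half served by its own tRNA — giving 22 families that partition the
60 sense codons and map one-to-one onto the 22 tRNA isotypes
(`trnaCodonMap()`). A zero-count family has undefined RSCU, reported
as `NA` rather than 0 (0 would read as an extreme bias). RSCU is
computed on the pooled 13-gene counts by default, with a per-gene
option.

The chi-square comparison of two genomes' usage is a 2×K homogeneity
test on pooled sense-codon counts, no Yates correction, with columns
of expected count below 1 pooled into an `other` column (configurable,
set `minExpected = 0` to disable). The smallest-cell rule must be
explicit for the test to be reproducible.

# tRNA position and the correlation test

The distance of a tRNA gene is the directed arc from the CR 3' end to
the tRNA 5' end, walked in annotation (heavy-strand transcription)
direction, modulo the genome length: positions just downstream of the
CR get small distances, genes upstream of the CR get large ones, and
nothing is negative. The directed arc (rather than the minimum arc,
available as `direction = "min"`) reflects the transcriptional
rationale of the test: what matters is how soon after the CR the
polymerase reaches the gene. For minus-strand tRNAs the 5' end is the
annotation-end coordinate. Distances are invariant under rotation of
the coordinate numbering — the numbering origin of a circular genome
is arbitrary. With duplicated CRs or tRNAs, the first copy in scan
order is analyzed (the first CR from coordinate zero; for tRNAs the
copy closest downstream of the CR).

One record per genome and functional tRNA isotype pairs distance with
the pooled usage of the codons that tRNA decodes (raw counts, not
frequencies — codon counts are the quantity the translational
hypothesis speaks about; a frequency option exists). A complete
vertebrate complement yields 22 records per genome — so 14 genomes
give n = 308 and a panel of genomes is pooled at the record level, not
averaged per species. Pearson and Spearman correlations are both
reported, two-tailed, with p-values from the t approximation on
n − 2 degrees of freedom; Spearman uses midranks, so with no ties it
equals Pearson on ranks exactly. Hydropathy classes (hydrophobic:
Gly, Ala, Val, Leu, Ile, Pro, Phe, Met, Trp, Cys) are used only for
grouping in reports, never in the statistics.

# Divergence (NG86)

`ng86Pairwise()` implements the Nei–Gojobori (1986) counting
estimator: per-codon synonymous site fractions from the code
(averaged between the two sequences), pathway-averaged synonymous and
nonsynonymous difference counts for codons differing at 2–3 positions,
proportions pS = Sd/S and pN = Nd/N, and the Jukes–Cantor correction
d = −(3/4)·ln(1 − (4/3)p). Conventions that the estimator's original
description leaves open are fixed as follows: single-nucleotide
changes that would create a stop codon count as nonsynonymous in the
site tally; mutation pathways passing through a stop codon are
excluded from averaging, with all pathways used as a fallback when
every path is blocked. ω = dN/dS is undefined (flagged `dS=0` or
`0/0`) rather than infinite when dS = 0, p ≥ 3/4 raises a saturation
error naming the gene, and an internal stop aborts that gene —
silently including a frameshifted pseudogene would corrupt site
counts. No alignment is performed: genome pairs are compared gene by
gene on length-matched sequences (true by construction for simulated
congeners; real data must be pre-aligned), and mismatched genes are
skipped with a message.

Group contrasts (e.g. rearranged vs ancestral-order genomes) default
to the two-sided Mann–Whitney U test — per-gene rates are few and not
normal — with Welch's t as an option; the test used is named in the
output.

# The synthetic-data generator

The simulator emulates the study conditions the pipeline is meant for:
circular genomes of ~16.5 kb with 13 protein-coding genes at anuran
codon counts (cox1 = 516 codons, nad5 = 605, atp8 = 55, ...), rRNAs of
930/1580 bp, 22 tRNA placeholders of 68–73 bp with canonical
anticodons, a CR of a random flank plus a 60 bp unit tandemly repeated
12 times (mirroring the repeat-rich CRs that frustrate sequencing of
real frog CRs), a 30 bp O~L~, optional pseudogene relics (default
62 bp, the size of the ψtrnS(AGY) relic in *Glandirana*-type genomes),
reference or TDRL-rearranged gene orders, and congeneric partners
evolved to target dS/dN. Every true parameter — codon counts per gene,
tRNA distances, codon sampling probabilities, TDRL events, applied
substitution counts — is recorded in a ledger.

The codon-usage model: each species draws 22 codon-family weights from
a symmetric Dirichlet (`usageAlphaFam`, default 60 — species-level
codon bias of realistic magnitude), splits each family across its
codons by a second Dirichlet (`usageAlpha`, default 10), and
multiplies each family weight by `exp(-beta * d/1000)` where *d* is
the species' true distance of the decoding tRNA from the CR. Family
weights are size-free, so at `beta = 0` every tRNA has the same
expected usage and the null correlation is clean; `beta` is the single
effect-size knob. Because usage is count data, a target correlation
cannot be hit exactly: `calibrateBeta()` searches a grid and reports
the realized value, and the realized pooled correlations recorded in
the ledger are computed with the same formulas the pipeline uses, so
pipeline recomputation from the emitted GenBank files must agree to
numerical precision (codon counts exactly, correlations to 1e-9 —
verified in the tests). The link is not monotone in `beta` without
bound: at extreme values distal families receive essentially zero
counts and the resulting ties erode the rank correlation, so the
usable range is roughly 0.01–1 per kb.

Partner evolution inverts the Jukes–Cantor map to target proportions,
draws Poisson numbers of synonymous and nonsynonymous events
(expectation pS·S and pN·N per gene), and applies them uniformly over
the currently available changes of each class, never creating stops.
In the low-divergence regime (every codon hit at most once) the NG86
difference counts equal the applied-event ledger exactly; at
dS = 0.10 multiple hits make the estimator recover targets to within
a few percent, comfortably inside the 10% band the recovery tests
assert over 20 pairs.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: tRNA placeholders have no cloverleaf
structure (no pipeline stage reads structure); rRNA and noncoding
sequences are i.i.d. random; base composition is unskewed (no strand
asymmetry or GC gradient); genes do not overlap; no indels, so real
pre-alignment issues are untested; and gene orders evolve only by the
TDRL mechanism.

# Numerical choices and problem sizes

* Rotation-invariant equality uses the lexicographically smallest
  rotation of the token signatures; ties in TDRL scenarios are ordered
  by cost, then leftmost interval.
* All randomness flows from a single seed through fixed substreams
  (seeds derived modulo 2^31), so every simulation, test and pipeline
  run is reproducible; pipeline outputs are byte-identical across
  reruns of the same config.
* The test and acceptance workloads use problem sizes chosen so each
  statistical property is measured where it is stable: exhaustive TDRL
  agreement on all segments of 2–6 genes (5,436 derivations); 1,000
  random tables/datasets for the RSCU and correlation numerics (checked
  to 1e-12); 14-genome panels (n = 308 records) for dataset
  cardinality; 20 simulated congeneric pairs of ~3,800 codons for
  divergence recovery and 50 replicates for the neutral-ω check;
  100 random genomes for rotation invariance.

# Known limitations

* TDRL inference requires unique functional gene names in the
  ancestral segment and searches single events only; nested or
  overlapping histories must be composed externally.
* The GenBank reader targets well-formed organelle records (LOCUS /
  FEATURES / ORIGIN, the location forms used by organelle annotation);
  it is not a general-purpose GenBank parser.
* NG86 is a counting estimator: it underestimates at high divergence
  and does not model transition/transversion or codon-frequency bias;
  maximum-likelihood codon models are out of scope.
* The correlation test pools records across species without
  phylogenetic correction; phylogenetically independent contrasts are
  out of scope.
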