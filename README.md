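# mitoRearr

Analysis of mitochondrial genome reorganization in frogs (and other
vertebrates): gene-order extraction and classification, tandem
duplication–random loss (TDRL) scenario inference, codon usage and
RSCU, the tRNA-position-vs-codon-usage test of adaptive gene order,
and pairwise dS/dN divergence — with a synthetic-mitogenome simulator
that makes the whole pipeline testable end to end without downloads.

## The scientific problem

Vertebrate mitogenomes are circular, ~15–18 kb, and usually carry 13
protein-coding genes, 2 rRNAs, 22 tRNAs, a control region (CR) and the
light-strand replication origin (O<sub>L</sub>) in a deeply conserved
arrangement (the ancestral gene order, AGO). Neobatrachian frogs break
this conservation: their mitogenomes share the rearranged
trnL(CUN)–trnT–trnP–trnF (*LTPF*) cluster next to the CR, and hotspots
such as the WANCY tRNA block (trnW–trnA–trnN–O<sub>L</sub>–trnC–trnY)
repeatedly spawn duplications, pseudogenes and gene losses. Two
questions follow:

1. **Mechanism** — can an observed rearranged order be explained by a
   single tandem duplication of a gene tract followed by random loss
   (pseudogenization or deletion) of redundant copies (the TDRL
   model)?
2. **Selection** — is gene *position* adaptive? If highly used tRNAs
   profit from sitting near the CR (where transcription starts),
   codon usage of the 13 protein-coding genes should correlate
   negatively with each tRNA's distance from the CR; and rearranged
   genomes should show elevated dN/dS if reorganization accompanies
   relaxed purifying selection.

`mitoRearr` implements the computational core of that analysis as a
reusable, tested R package.

## Methods at the core

* **Gene orders.** A genome's organization is a circular token
  sequence (name, strand, pseudogene flag). Orders are compared by
  rotation-invariant equality and a strand-aware shared-adjacency
  distance; classification against the vertebrate AGO reports named
  diagnostics (LTPF cluster, WANCY integrity, trnH translocation,
  duplications, losses, pseudogenes).
* **TDRL inference.** For an ancestral segment *A* and derived segment
  *D*, `inferTDRL()` returns every minimal-cost single-TDRL scenario:
  a duplicated interval of *A* and per-copy fates
  (retained / pseudogenized / deleted, exactly one copy of each gene
  retained) whose forward application reproduces *D* exactly. Cost is
  lexicographic: fewest duplicated genes, then fewest non-retained
  copies; ties are all reported.
* **Codon usage and RSCU.** Codons of the 13 protein-coding genes are
  counted per gene in each gene's own frame and strand under the
  vertebrate mitochondrial code (AGA/AGG stop, AUA Met, UGA Trp). RSCU
  for codon *c* in synonymous family *F* of size *n* is
  RSCU(c) = x_c / ((1/n) Σ_{c'∈F} x_{c'}), with leucine split into
  CUN/UUR and serine into AGY/UCN families, matching their two tRNAs.
  The 22 families partition the 60 sense codons and map one-to-one
  onto the 22 tRNA isotypes.
* **Position–usage correlation.** Each tRNA's distance is the directed
  arc from the CR 3' end to the tRNA 5' end (annotation direction,
  modulo genome length; first copies only; pseudogenes excluded).
  Pearson and Spearman correlations (two-tailed, t approximation,
  n − 2 df) relate distance to the pooled usage of the codons each
  tRNA decodes.
* **Divergence.** Pairwise dS and dN follow Nei & Gojobori (1986):
  per-codon synonymous site fractions, pathway-averaged difference
  counts for multi-hit codons, p = d/sites, and the Jukes–Cantor
  correction d = −(3/4)·ln(1 − (4/3)p); ω = dN/dS. Group contrasts use
  a two-sided Mann–Whitney U test.
* **Simulator.** `simSpec()` / `generateGenome()` build annotated
  circular genomes with anuran-style gene complements, TDRL-derived
  orders, pseudogene relics, a per-species codon-usage model with a
  tunable distance link (family weight ∝ exp(−β·distance)), and
  congeneric partners evolved to target dS/dN — with every true
  parameter recorded in a ledger.

## Worked example

```r
library(mitoRearr)

## 1. Simulate a panel: 3 AGO genomes and 3 neobatrachian-style
##    genomes, with codon usage linked to tRNA position (beta = 0.25/kb)
spec <- simSpec(seed = 7, nSpecies = 6,
                orders = c("vertebrate_AGO", "neobatrachian_LTPF"),
                beta = 0.25)
sim <- generateCorrelatedSet(spec)

## 2. Gene-order classification
cls <- classifyOrder(extractGeneOrder(sim$genomes[[2]]))
cat(cls$label, "|", paste(cls$features, collapse = ", "), "\n")
#> RGO | WANCY_intact, LTPF_cluster

## 3. TDRL reconstruction of the Amolops-style WANCY rearrangement
inferTDRL(parseOrderString("WANO_L_CY"),
          parseOrderString("WA'N'O_L_ANO_L_'CY"))[[1]]
#> TDRLScenario: tandem duplication of 3 gene(s) [2..4], cost (3, 3)
#>   copy 1: trnA' trnN' OL
#>   copy 2: trnA trnN OL'

## 4. RSCU and the position-usage correlation
head(rscu(countCodons(sim$genomes[[1]])), 4)
#>   codon aa family count      rscu
#> 1   GCA  A   trnA    56 1.1370558
#> 2   GCC  A   trnA    60 1.2182741
#> 3   GCG  A   trnA    31 0.6294416
#> 4   GCT  A   trnA    50 1.0152284
res <- correlateUsage(assembleDataset(sim$genomes))
cat(sprintf("pooled: r = %.3f, rho = %.3f, n = %d\n",
            res$pearson_r, res$spearman_rho, res$n))
#> pooled: r = -0.840, rho = -0.974, n = 132

## 5. dS/dN against an evolved congeneric partner
pair <- evolvePair(sim$genomes[[1]], targetDS = 0.10, targetDN = 0.02,
                   seed = 99)
dv <- genomePairDivergence(sim$genomes[[1]], pair$genome)
head(dv[, c("gene", "codons", "dS", "dN", "omega")], 5)
#>   gene codons     dS     dN  omega
#> 1 nad1    322 0.0894 0.0232 0.2595
#> 2 nad2    344 0.1014 0.0222 0.2185
#> 3 cox1    516 0.0986 0.0257 0.2608
#> 4 cox2    230 0.0866 0.0214 0.2477
#> 5 atp8     55 0.1086 0.0074 0.0684
```

The scenario in step 3 is the parsimonious explanation of the order
`W A' N' OL A N OL' C Y`: one tandem duplication of `trnA–trnN–OL`
whose first copies of trnA/trnN and second copy of O<sub>L</sub>
degenerated into pseudogenes. In step 4 the strongly negative pooled
correlation recovers the simulated CR-proximity effect; in step 5 the
per-gene NG86 estimates scatter around the simulated targets
(dS = 0.10, dN = 0.02, so ω ≈ 0.2, purifying-selection territory).

`runPipeline(config)` chains these stages (simulate/read → orders →
codon usage/RSCU → correlations → TDRL → dN/dS) into a deterministic
output directory; see `?runPipeline`.

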