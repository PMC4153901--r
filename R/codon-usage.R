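# Codon counting of mitochondrial protein-coding genes under the
# vertebrate mitochondrial code, RSCU with the Leu/Ser split-family
# convention, per-tRNA usage aggregation, and the chi-square
# codon-usage homogeneity comparison.

#' Count codons of the protein-coding genes of a genome
#'
#' Each annotated CDS is read in its own frame from its own strand
#' (reverse complement for `-` strand genes, wrapping the origin where
#' needed). A terminal stop codon and any incomplete terminal codon
#' (1-2 nt) are excluded. Codons are enumerated once per gene, so
#' nucleotides shared by physically overlapping genes (atp8/atp6 style)
#' contribute to both genes' tables; set `overlapOnce = TRUE` to count
#' codons fully contained in an earlier gene's span only for that
#' earlier gene. Codons containing ambiguity characters are skipped and
#' tallied. An internal stop codon triggers a warning and flags the
#' gene (pseudogene suspicion) but is not fatal; the stop codon itself
#' is not counted.
#'
#' @param genome a [MitoGenome-class] object with a sequence.
#' @param overlapOnce alternative reading of overlap handling (default
#'   `FALSE`: per-gene enumeration).
#' @return a [CodonUsageTable-class] object.
#' @export
countCodons <- function(genome, overlapOnce = FALSE) {
  if (is.na(genome@sequence))
    stop("genome has no sequence: ", genome@id)
  f <- genome@features
  cds <- f[f$kind == "CDS" & !f$pseudo, , drop = FALSE]
  L <- genome@length
  stops <- mitoStopCodons()
  perGene <- list()
  flagged <- character(0)
  ambig <- 0L
  claimed <- rep(FALSE, L) # nt positions already inside an earlier CDS
  for (i in seq_len(nrow(cds))) {
    nt <- .circSubstr(genome@sequence, cds$start[i], cds$end[i], L)
    if (cds$strand[i] == "-") nt <- .revcomp(nt)
    codons <- .codonSplit(nt)
    if (length(codons) && codons[length(codons)] %in% stops)
      codons <- codons[-length(codons)]
    if (overlapOnce) {
      flen <- .featLength(cds$start[i], cds$end[i], L)
      pos <- (.modLen(cds$start[i] + seq_len(flen) - 1L, L)) + 1L
      codIdx <- if (cds$strand[i] == "+")
        split(pos, ceiling(seq_len(flen) / 3L))
      else split(rev(pos), ceiling(seq_len(flen) / 3L))
      keepCodon <- !vapply(codIdx[seq_along(codons)],
                           function(p) all(claimed[p]), logical(1))
      codons <- codons[keepCodon]
      claimed[pos] <- TRUE
    }
    okDna <- .isDNA(codons)
    ambig <- ambig + sum(!okDna)
    codons <- codons[okDna]
    isStop <- codons %in% stops
    if (any(isStop)) {
      warning(sprintf(
        "internal stop codon(s) in %s of '%s' (pseudogene suspicion)",
        cds$name[i], genome@id))
      flagged <- c(flagged, cds$name[i])
      codons <- codons[!isStop]
    }
    cnt <- table(codons)
    gname <- cds$name[i]
    if (cds$copy[i] > 1L) gname <- sprintf("%s.%d", gname, cds$copy[i])
    perGene[[gname]] <- setNames(as.numeric(cnt), names(cnt))
  }
  allCodons <- sort(unique(unlist(lapply(perGene, names))))
  pooled <- setNames(numeric(length(allCodons)), allCodons)
  for (g in perGene) pooled[names(g)] <- pooled[names(g)] + g
  new("CodonUsageTable", genomeId = genome@id, perGene = perGene,
      pooled = pooled, totalCodons = sum(pooled),
      ambiguousSkipped = as.numeric(ambig),
      internalStopGenes = unique(flagged))
}

#' Relative synonymous codon usage
#'
#' For codon c in synonymous family F (of size n), RSCU(c) =
#' x_c / ((1/n) * sum of x over F). Families are the synonymous
#' families of the vertebrate mitochondrial code with leucine split
#' into CUN and UUR families and serine into AGY and UCN families,
#' matching their two distinct tRNAs. A family with zero total count
#' has undefined RSCU (reported as `NA`, not 0). Within any family with
#' positive total, the RSCU values average to 1 and sum to the family
#' size.
#'
#' @param table a [CodonUsageTable-class] object, or a named numeric
#'   vector of codon counts.
#' @param gene optionally restrict to one gene's counts instead of the
#'   pooled table.
#' @return data.frame with columns `codon`, `aa`, `family`, `count`,
#'   `rscu`, one row per sense codon, in family order.
#' @export
rscu <- function(table, gene = NULL) {
  counts <- if (is(table, "CodonUsageTable")) {
    if (is.null(gene)) table@pooled
    else {
      if (!gene %in% names(table@perGene))
        stop("no such gene in table: ", gene)
      table@perGene[[gene]]
    }
  } else table
  fam <- .codonFamily()
  code <- mitoGeneticCode()
  full <- setNames(numeric(length(fam)), names(fam))
  hit <- intersect(names(counts), names(full))
  full[hit] <- counts[hit]
  out <- data.frame(codon = names(fam), aa = unname(code[names(fam)]),
                    family = unname(fam), count = unname(full),
                    stringsAsFactors = FALSE)
  out <- out[order(out$family, out$codon), , drop = FALSE]
  totals <- tapply(out$count, out$family, sum)
  sizes <- tapply(out$count, out$family, length)
  famTot <- totals[out$family]
  famSize <- sizes[out$family]
  out$rscu <- as.numeric(
    ifelse(famTot > 0, out$count / (famTot / famSize), NA_real_))
  rownames(out) <- NULL
  out
}

#' Aggregate codon usage per decoding tRNA
#'
#' Sums the pooled codon counts over each tRNA's codon set. Because the
#' 22 codon sets partition the sense codons, the 22 usage values sum to
#' the table's total codon count.
#'
#' @param table a [CodonUsageTable-class] object.
#' @param map tRNA-to-codon map, default [trnaCodonMap()].
#' @return named numeric vector: tRNA token -> codon count.
#' @export
usageByTrna <- function(table, map = trnaCodonMap()) {
  counts <- if (is(table, "CodonUsageTable")) table@pooled else table
  vapply(map, function(codons) {
    sum(counts[intersect(codons, names(counts))])
  }, numeric(1))
}

#' Chi-square comparison of codon usage between two genomes
#'
#' Pearson chi-square test of homogeneity on the 2 x K table of pooled
#' sense-codon counts (no Yates correction). Codon columns with zero
#' counts in both genomes are dropped; columns whose expected count
#' falls below `minExpected` in either row are pooled into an "other"
#' column. Degrees of freedom are K' - 1.
#'
#' @param a,b [CodonUsageTable-class] objects (or named count vectors).
#' @param minExpected pooling threshold for small expected counts
#'   (default 1; set to 0 to disable pooling).
#' @return list with `chi2`, `df`, `p` (two-tailed), and `K` (number of
#'   codon columns used).
#' @export
compareUsageChi2 <- function(a, b, minExpected = 1) {
  ca <- if (is(a, "CodonUsageTable")) a@pooled else a
  cb <- if (is(b, "CodonUsageTable")) b@pooled else b
  if (!length(ca) || !length(cb)) stop("empty codon usage table")
  codons <- sort(union(names(ca), names(cb)))
  m <- rbind(a = setNames(numeric(length(codons)), codons),
             b = setNames(numeric(length(codons)), codons))
  m["a", names(ca)] <- ca
  m["b", names(cb)] <- cb
  m <- m[, colSums(m) > 0, drop = FALSE]
  if (ncol(m) >= 2L && minExpected > 0) {
    expected <- outer(rowSums(m), colSums(m)) / sum(m)
    small <- apply(expected < minExpected, 2L, any)
    if (sum(small) > 1L) {
      pooledCol <- rowSums(m[, small, drop = FALSE])
      m <- cbind(m[, !small, drop = FALSE], other = pooledCol)
    }
  }
  if (ncol(m) < 2L)
    stop("fewer than 2 usable codon columns; cannot compare usage")
  ht <- suppressWarnings(chisq.test(m, correct = FALSE))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = if (unname(ht$statistic) == 0) 1 else unname(ht$p.value),
       K = ncol(m))
}
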