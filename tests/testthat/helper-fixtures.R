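# Fixture builders shared across the test files. Everything is built
# in code; no binary fixtures.

# A minimal hand-built genome: one CDS, one tRNA, one CR, with an
# explicit sequence. codingSeq is placed on the requested strand.
tinyGenome <- function(codingSeq = "ATGATAATGTAA", strand = "+",
                       id = "TINY1") {
  nCod <- nchar(codingSeq)
  trnaSeq <- paste(rep("ACGT", 17), collapse = "")  # 68 bp
  crSeq <- paste(rep("TTAACC", 50), collapse = "")  # 300 bp
  cdsOnGenome <- if (strand == "-")
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(codingSeq)))
  else codingSeq
  seqStr <- paste0(cdsOnGenome, trnaSeq, crSeq)
  feats <- data.frame(
    name = c("cox1", "trnF", "CR"),
    kind = c("CDS", "tRNA", "CR"),
    strand = c(strand, "+", "+"),
    start = c(0L, nCod, nCod + 68L),
    end = c(nCod, nCod + 68L, nCod + 68L + 300L),
    pseudo = FALSE,
    anticodon = c(NA, "GAA", NA),
    stringsAsFactors = FALSE)
  newMitoGenome(id, nchar(seqStr), feats, sequence = seqStr)
}

# Rotate a genome's coordinate numbering by k bp (the base at old
# position k becomes position 0). Biology is unchanged.
rotateGenome <- function(genome, k) {
  L <- genomeLength(genome)
  k <- k %% L
  if (k == 0L) return(genome)
  f <- features(genome)
  f$start <- (f$start - k) %% L
  f$end <- (f$end - k) %% L
  s <- genomeSequence(genome)
  s2 <- if (is.na(s)) NA_character_ else
    paste0(substr(s, k + 1L, L), substr(s, 1L, k))
  newMitoGenome(genomeId(genome), L, f, sequence = s2,
                circular = genome@circular)
}

# Hand-written GenBank record text for parser tests.
gbFixture <- function(id = "FIX1", length = 1000L, circular = TRUE,
                      featureLines = character(0), sequence = NULL) {
  txt <- c(sprintf("LOCUS       %s  %d bp    DNA     %s     UNA",
                   id, length, if (circular) "circular" else "linear"),
           "FEATURES             Location/Qualifiers",
           featureLines)
  if (!is.null(sequence)) {
    txt <- c(txt, "ORIGIN")
    s <- tolower(sequence)
    starts <- seq(1L, nchar(s), by = 60L)
    for (st in starts)
      txt <- c(txt, sprintf("%9d %s", st,
                            substr(s, st, min(st + 59L, nchar(s)))))
  }
  c(txt, "//")
}

randomCodonCounts <- function(lambda = 20) {
  sense <- mitoSenseCodons()
  setNames(as.numeric(rpois(length(sense), lambda)), sense)
}

randomUsageTable <- function(lambda = 20, id = "R1") {
  counts <- randomCodonCounts(lambda)
  new("CodonUsageTable", genomeId = id,
      perGene = list(g1 = counts), pooled = counts,
      totalCodons = sum(counts), ambiguousSkipped = 0,
      internalStopGenes = character(0))
}
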