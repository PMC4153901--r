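test_that("codons are counted per gene with terminal stop excluded", {
  g <- tinyGenome("ATGATAATGTAA")
  tb <- countCodons(g)
  expect_equal(tb@pooled[["ATG"]], 2)
  expect_equal(tb@pooled[["ATA"]], 1)
  expect_equal(tb@totalCodons, 3)
  expect_false("TAA" %in% names(tb@pooled))
  # identical counting on the minus strand
  tbm <- countCodons(tinyGenome("ATGATAATGTAA", strand = "-"))
  expect_equal(tbm@pooled, tb@pooled)
  # no sequence is an error
  g2 <- newMitoGenome("X", genomeLength(g), features(g))
  expect_error(countCodons(g2), "sequence")
})

test_that("an incomplete terminal codon is dropped (brute-force check)", {
  set.seed(4)
  sense <- mitoSenseCodons()
  codons <- sample(sense, 40, replace = TRUE)
  cds <- paste0(paste(codons, collapse = ""), "AT") # 3k + 2 nt
  g <- tinyGenome(cds)
  tb <- countCodons(g)
  expect_equal(tb@totalCodons, 40)
  naive <- table(codons)
  expect_equal(tb@pooled[names(naive)], setNames(as.numeric(naive),
                                                 names(naive)))
})

test_that("overlapping genes contribute overlap codons to both tables", {
  # atp8/atp6-style 10 nt overlap; both genes in frame on their spans
  a <- "ATGAAACCCGGGTTTACT"              # 18 nt
  bTail <- "GCAGCCGCGTAA"
  seqStr <- paste0(a, bTail, strrep("C", 300))
  feats <- data.frame(
    name = c("atp8", "atp6", "CR"),
    kind = c("CDS", "CDS", "CR"),
    strand = "+",
    start = c(0L, 9L, 30L),
    end = c(18L, 30L, 330L),
    pseudo = FALSE, stringsAsFactors = FALSE)
  g <- newMitoGenome("OVL", 330L, feats, sequence = seqStr)
  tb <- countCodons(g)
  expect_equal(sum(tb@perGene$atp8), 6)
  expect_equal(sum(tb@perGene$atp6), 6) # 7 codons minus the stop
  # the shared codons GGG and TTT appear in both genes' tables
  expect_equal(tb@perGene$atp8[["GGG"]], 1)
  expect_equal(tb@perGene$atp6[["GGG"]], 1)
  # the overlap-once switch removes fully shared codons from atp6
  tb1 <- countCodons(g, overlapOnce = TRUE)
  expect_equal(sum(tb1@perGene$atp8), 6)
  expect_lt(sum(tb1@perGene$atp6), 6)
})

test_that("internal stop codons warn and flag the gene", {
  expect_warning(tb <- countCodons(tinyGenome("ATGAGAATGTAA")),
                 "internal stop")
  expect_equal(tb@internalStopGenes, "cox1")
  expect_equal(tb@totalCodons, 2) # AGA excluded from counts
  # ambiguity codons are skipped and tallied
  tb2 <- countCodons(tinyGenome("ATGANAATGTAA"))
  expect_equal(tb2@ambiguousSkipped, 1)
  expect_equal(tb2@totalCodons, 2)
})

test_that("RSCU follows the split-family definition", {
  counts <- setNames(numeric(0), character(0))
  counts[c("GGA", "GGC", "GGG", "GGT")] <- c(8, 0, 0, 0)
  r <- rscu(counts)
  expect_equal(r$rscu[r$codon == "GGA"], 4)
  expect_equal(r$rscu[r$codon == "GGC"], 0)
  # equal nonzero counts give RSCU 1 everywhere in the family
  r2 <- rscu(setNames(c(3, 3, 3, 3), c("CCA", "CCC", "CCG", "CCT")))
  expect_equal(r2$rscu[r2$family == "trnP"], rep(1, 4))
  # Leu split: CUN and UUR are separate families
  counts3 <- setNames(c(2, 1, 1, 0, 5, 1),
                      c("CTT", "CTC", "CTA", "CTG", "TTA", "TTG"))
  r3 <- rscu(counts3)
  expect_equal(r3$rscu[r3$codon == "CTT"], 2)
  expect_equal(r3$rscu[r3$codon == "TTA"], 5 / 3)
  # zero-count family is NA, not 0
  expect_true(all(is.na(r3$rscu[r3$family == "trnK"])))
})

test_that("RSCU normalization holds on random tables", {
  set.seed(11)
  for (i in 1:50) {
    r <- rscu(randomCodonCounts())
    for (fam in unique(r$family)) {
      sub <- r[r$family == fam, ]
      if (sum(sub$count) == 0) next
      expect_equal(mean(sub$rscu), 1, tolerance = 1e-12)
      expect_equal(sum(sub$rscu), nrow(sub), tolerance = 1e-12)
    }
  }
})

test_that("per-tRNA usage partitions the total codon count", {
  u <- usageByTrna(setNames(c(2, 3), c("ATG", "ATA")))
  expect_equal(u[["trnM"]], 5)
  expect_equal(sum(u), 5)
  set.seed(12)
  for (i in 1:20) {
    tb <- randomUsageTable()
    expect_equal(sum(usageByTrna(tb)), tb@totalCodons)
  }
  # the 22 codon sets partition the 60 sense codons
  map <- trnaCodonMap()
  expect_equal(length(map), 22L)
  expect_setequal(unlist(map), mitoSenseCodons())
  expect_equal(anyDuplicated(unlist(map)), 0L)
})

test_that("chi-square usage comparison matches hand computation", {
  a <- setNames(c(10, 10), c("AAA", "CCC"))
  expect_equal(compareUsageChi2(a, a, minExpected = 0)$chi2, 0)
  expect_equal(compareUsageChi2(a, a, minExpected = 0)$p, 1)
  expect_equal(compareUsageChi2(a, a * 3, minExpected = 0)$chi2, 0)
  h <- compareUsageChi2(setNames(c(30, 10), c("AAA", "CCC")),
                        setNames(c(10, 30), c("AAA", "CCC")),
                        minExpected = 0)
  expect_equal(h$chi2, 20) # all four expected cells are 20
  expect_equal(h$df, 1)
  expect_error(compareUsageChi2(setNames(5, "AAA"), setNames(5, "AAA")),
               "columns")
})
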