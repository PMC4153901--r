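test_that("a tRNA starting right after the CR 3' end is at distance 0", {
  # CR occupies [100, 400); trnF starts at 400
  seqStr <- strrep("ACGT", 200)
  feats <- data.frame(
    name = c("cox1", "CR", "trnF"),
    kind = c("CDS", "CR", "tRNA"),
    strand = "+", start = c(0L, 100L, 400L), end = c(99L, 400L, 468L),
    pseudo = FALSE, stringsAsFactors = FALSE)
  g <- newMitoGenome("D0", 800L, feats, sequence = seqStr)
  d <- trnaCrDistances(g)
  expect_equal(d[["trnF"]], 0)
  # minus-strand tRNA: 5' end is the annotation end
  feats$strand[3] <- "-"
  gm <- newMitoGenome("D1", 800L, feats, sequence = seqStr)
  expect_equal(trnaCrDistances(gm)[["trnF"]], 67)
  # missing CR errors with the genome named
  expect_error(trnaCrDistances(newMitoGenome("D2", 800L, feats[-2, ],
                                             sequence = seqStr)),
               "D2")
})

test_that("only first copies of duplicated CRs and tRNAs are analyzed", {
  feats <- data.frame(
    name = c("CR", "trnM", "trnM", "CR", "trnF"),
    kind = c("CR", "tRNA", "tRNA", "CR", "tRNA"),
    strand = "+",
    start = c(0L, 300L, 500L, 700L, 1100L),
    end = c(200L, 368L, 568L, 900L, 1168L),
    pseudo = FALSE, stringsAsFactors = FALSE)
  g <- newMitoGenome("DUP", 1200L, feats, sequence = strrep("A", 1200L))
  d <- trnaCrDistances(g)
  # distances from the first CR's 3' end (position 200)
  expect_equal(d[["trnM"]], 100)   # first trnM copy only
  expect_equal(d[["trnF"]], 900)
  expect_equal(length(d), 2L)
})

test_that("distances are invariant under coordinate rotation", {
  spec <- simSpec(seed = 21, nSpecies = 1)
  g <- generateGenome(spec, 1)$genome
  d0 <- trnaCrDistances(g)
  set.seed(33)
  for (k in sample(genomeLength(g) - 1L, 6L)) {
    dk <- trnaCrDistances(rotateGenome(g, k))
    expect_equal(dk[names(d0)], d0)
  }
})

test_that("dataset assembly yields one record per functional tRNA isotype", {
  spec <- simSpec(seed = 22, nSpecies = 3)
  genomes <- lapply(1:3, function(i) generateGenome(spec, i)$genome)
  ds <- assembleDataset(genomes)
  expect_equal(nrow(ds), 3L * 22L)
  expect_setequal(unique(ds$trna), trnaTokens())
  expect_true(all(ds$usage >= 0) && all(ds$distance >= 0))
  # pseudogenized trnS(AGY) drops one record
  specP <- simSpec(seed = 22, nSpecies = 1,
                   orders = "neobatrachian_LTPF",
                   pseudogenize = "trnS(AGY)")
  gP <- generateGenome(specP, 1)$genome
  expect_equal(nrow(assembleDataset(list(gP))), 21L)
  expect_equal(sort(unique(assembleDataset(list(gP))$hydropathy)),
               c("hydrophilic", "hydrophobic"))
})

test_that("correlations match the direct formulas and handle edge cases", {
  # strictly monotone decreasing usage: Spearman rho = -1
  recs <- data.frame(distance = c(10, 200, 3000, 8000, 12000),
                     usage = c(50, 40, 22, 7, 1))
  res <- correlateUsage(recs)
  expect_equal(res$spearman_rho, -1)
  # perfect linear positive: Pearson r = 1
  recs2 <- data.frame(distance = 1:8, usage = 3 + 2 * (1:8))
  expect_equal(correlateUsage(recs2)$pearson_r, 1)
  # random datasets against the direct-formula oracle
  set.seed(14)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    recs <- data.frame(distance = sample.int(16000, n, replace = TRUE),
                       usage = rpois(n, 40))
    if (length(unique(recs$usage)) < 2) next
    res <- correlateUsage(recs)
    ora <- corOracle(recs$distance, recs$usage)
    expect_equal(res$pearson_r, unname(ora["r"]), tolerance = 1e-12)
    expect_equal(res$spearman_rho, unname(ora["rho"]),
                 tolerance = 1e-12)
    expect_equal(res$n, n)
  }
  expect_error(correlateUsage(data.frame(distance = c(1, 1, 1),
                                         usage = c(1, 2, 3))),
               "constant")
  expect_error(correlateUsage(data.frame(distance = 1:2, usage = 2:1)),
               "3 records")
})

test_that("the correlation report covers sets, species and hydropathy", {
  spec <- simSpec(seed = 25, nSpecies = 2)
  genomes <- lapply(1:2, function(i) generateGenome(spec, i)$genome)
  rep1 <- correlationReport(list(ago = genomes))
  expect_true("pooled" %in% rep1$scope)
  sp <- rep1[rep1$scope == "SIM001", ]
  expect_equal(sp$n, 22)
  # results do not depend on how sets are named
  rep2 <- correlationReport(list(renamed = genomes))
  expect_equal(rep1[, -1], rep2[, -1])
  expect_error(correlationReport(list(genomes)), "named")
  expect_error(correlationReport(list(a = list())), "empty")
})
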