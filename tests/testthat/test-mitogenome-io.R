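test_that("a GenBank fixture parses into features in scan order", {
  feat <- c(
    "     CDS             10..120",
    '                     /gene="COX1"',
    "     tRNA            130..198",
    '                     /product="tRNA-Phe"',
    '                     /anticodon="GAA"',
    "     D-loop          210..500",
    '                     /note="control region"')
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(gbFixture(featureLines = feat), path)
  g <- readGenBank(path)[[1]]
  f <- features(g)
  expect_equal(nrow(f), 3L)
  expect_equal(f$name, c("cox1", "trnF", "CR"))
  expect_equal(f$kind, c("CDS", "tRNA", "CR"))
  expect_equal(f$start, c(9L, 129L, 209L))   # 0-based
  expect_equal(f$end, c(120L, 198L, 500L))   # half-open
  expect_true(g@circular)
  # parsing is insensitive to qualifier order
  feat2 <- c(
    "     CDS             10..120",
    '                     /gene="COX1"',
    "     tRNA            130..198",
    '                     /anticodon="GAA"',
    '                     /product="tRNA-Phe"',
    "     D-loop          210..500",
    '                     /note="control region"')
  path2 <- withr::local_tempfile(fileext = ".gb")
  writeLines(gbFixture(featureLines = feat2), path2)
  expect_equal(features(readGenBank(path2)[[1]]), f)
})

test_that("pseudogene qualifiers and tRNA-Ser isotypes are resolved", {
  feat <- c(
    "     tRNA            100..161",
    '                     /product="tRNA-Ser"',
    '                     /anticodon="GCT"',
    "                     /pseudo")
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(gbFixture(featureLines = feat), path)
  f <- features(readGenBank(path)[[1]])
  expect_equal(f$name, "trnS(AGY)")
  expect_true(f$pseudo)
  # unknown gene names are kept as noncoding, with a warning
  featU <- c("     misc_feature    100..200",
             '                     /gene="mystery7"')
  pathU <- withr::local_tempfile(fileext = ".gb")
  writeLines(gbFixture(featureLines = featU), pathU)
  expect_warning(gU <- readGenBank(pathU)[[1]], "unknown gene name")
  expect_equal(features(gU)$kind, "noncoding")
  expect_equal(features(gU)$name, "mystery7")
})

test_that("coordinates beyond a linear record's length are an error", {
  feat <- c("     CDS             900..1200",
            '                     /gene="COX1"')
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(gbFixture(length = 1000L, circular = FALSE,
                       featureLines = feat), path)
  expect_error(readGenBank(path), "outside")
  expect_error(readGenBank(withr::local_tempfile(fileext = ".txt")),
               "no such file")
})

test_that("write/read GenBank round-trips simulated genomes exactly", {
  spec <- simSpec(seed = 3, nSpecies = 1, orders = "neobatrachian_LTPF",
                  pseudogenize = "trnS(AGY)")
  g <- generateGenome(spec, 1)$genome
  for (k in c(0L, 5000L)) {
    gr <- rotateGenome(g, k) # k > 0 makes the CR wrap the origin
    path <- withr::local_tempfile(fileext = ".gb")
    writeGenBank(gr, path)
    g2 <- readGenBank(path)[[1]]
    expect_identical(genomeId(g2), genomeId(gr))
    expect_identical(genomeLength(g2), genomeLength(gr))
    expect_identical(genomeSequence(g2), genomeSequence(gr))
    expect_equal(features(g2), features(gr))
  }
})

test_that("the gene-order table round-trips and marks pseudogenes", {
  spec <- simSpec(seed = 5, nSpecies = 2,
                  orders = c("vertebrate_AGO", "neobatrachian_LTPF"),
                  pseudogenize = "trnS(AGY)")
  genomes <- lapply(1:2, function(i) generateGenome(spec, i)$genome)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeGeneOrderTable(genomes, path)
  back <- readGeneOrderTable(path)
  expect_equal(length(back), 2L)
  for (i in 1:2) {
    ord <- extractGeneOrder(genomes[[i]])
    expect_identical(orderTokenStrings(back[[i]]),
                     orderTokenStrings(ord))
  }
  expect_true("trnS(AGY)'" %in% orderTokenStrings(back[[1]]))
  expect_error(writeGeneOrderTable(list(), path), "empty")
})
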