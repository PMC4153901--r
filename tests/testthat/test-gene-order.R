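test_that("reference orders carry the canonical blocks", {
  ago <- referenceOrder("vertebrate_AGO")
  toks <- orderTokens(ago)$name
  expect_equal(sum(toks %in% trnaTokens()), 22L)
  wancy <- c("trnW", "trnA", "trnN", "OL", "trnC", "trnY")
  hit <- which(toks == "trnW")
  expect_equal(toks[hit:(hit + 5L)], wancy)
  ltpf <- referenceOrder("neobatrachian_LTPF")
  toks2 <- orderTokens(ltpf)$name
  hit2 <- which(toks2 == "trnL(CUN)")
  expect_equal(toks2[hit2:(hit2 + 3L)],
               c("trnL(CUN)", "trnT", "trnP", "trnF"))
  # the two references differ only by the LTPF tRNA placement
  expect_setequal(toks, toks2)
  expect_error(referenceOrder("chicken"), "vertebrate_AGO")
})

test_that("gene-order equality is rotation invariant", {
  ago <- referenceOrder("vertebrate_AGO")
  tk <- orderTokens(ago)
  for (k in c(1L, 7L, 20L, 38L)) {
    rot <- newGeneOrder(tk[c((k + 1L):nrow(tk), 1L:k),
                           c("name", "strand", "pseudo")])
    expect_true(orderEqual(ago, rot))
  }
  expect_false(orderEqual(ago, referenceOrder("neobatrachian_LTPF")))
})

test_that("extractGeneOrder recovers the layout order and drops short spacers", {
  spec <- simSpec(seed = 8, nSpecies = 1)
  g <- generateGenome(spec, 1)$genome
  expect_true(orderEqual(extractGeneOrder(g),
                         referenceOrder("vertebrate_AGO")))
  # coordinate rotation leaves the extracted order unchanged
  set.seed(42)
  for (k in sample(genomeLength(g) - 1L, 4L)) {
    expect_true(orderEqual(extractGeneOrder(rotateGenome(g, k)),
                           extractGeneOrder(g)))
  }
  # a pseudogene relic is a flagged token, not a spacer
  spec2 <- simSpec(seed = 8, nSpecies = 1, orders = "neobatrachian_LTPF",
                   pseudogenize = "trnS(AGY)")
  g2 <- generateGenome(spec2, 1)$genome
  toks <- orderTokenStrings(extractGeneOrder(g2))
  expect_true("trnS(AGY)'" %in% toks)
  expect_false("spacer" %in% toks)
  # an annotated noncoding stretch above the threshold is reported
  f <- features(g2)
  relic <- which(f$name == "trnS(AGY)")
  f$pseudo[relic] <- FALSE
  f$name[relic] <- "igs1"
  f$kind[relic] <- "noncoding"
  g3 <- newMitoGenome("SP1", genomeLength(g2), f,
                      sequence = genomeSequence(g2))
  expect_true("spacer" %in%
                orderTokenStrings(extractGeneOrder(g3)))
  expect_false("spacer" %in%
                 orderTokenStrings(extractGeneOrder(g3, spacerMin = 100L)))
})

test_that("classifyOrder separates AGO from rearranged orders", {
  ago <- referenceOrder("vertebrate_AGO")
  cls <- classifyOrder(ago)
  expect_equal(cls$label, "AGO")
  expect_equal(cls$features, "WANCY_intact")
  expect_equal(cls$lost, character(0))
  cls2 <- classifyOrder(referenceOrder("neobatrachian_LTPF"))
  expect_equal(cls2$label, "RGO")
  expect_true("LTPF_cluster" %in% cls2$features)
  # four tRNA losses are all reported
  tk <- orderTokens(referenceOrder("neobatrachian_LTPF"))
  tk <- tk[!tk$name %in% c("trnA", "trnN", "trnC", "trnE"), ]
  cls3 <- classifyOrder(newGeneOrder(tk[, c("name", "strand", "pseudo")]))
  expect_equal(cls3$label, "RGO")
  expect_setequal(cls3$lost, c("trnA", "trnN", "trnC", "trnE"))
  # any single TDRL event away from the AGO is rearranged
  for (s in 1:5) {
    rt <- applyRandomTDRL(ago, 1L, seed = s)
    expect_equal(classifyOrder(rt$order)$label, "RGO")
  }
})

test_that("adjacency distance is rotation invariant and matches a naive scan", {
  ago <- referenceOrder("vertebrate_AGO")
  ltpf <- referenceOrder("neobatrachian_LTPF")
  expect_equal(adjacencyDistance(ago, ago), 0L)
  tk <- orderTokens(ago)
  rot <- newGeneOrder(tk[c(12:nrow(tk), 1:11),
                         c("name", "strand", "pseudo")])
  expect_equal(adjacencyDistance(ago, rot), 0L)
  # independent naive adjacency-set comparison
  naive <- function(a, b) {
    pairsOf <- function(o) {
      tk <- orderTokens(o)
      tk <- tk[!tk$pseudo, ]
      sig <- paste0(tk$strand, tk$name)
      sort(paste(sig, c(sig[-1], sig[1]), sep = ">"))
    }
    pa <- pairsOf(a)
    pb <- pairsOf(b)
    oneWay <- function(u, v) {
      n <- 0L
      for (p in unique(u)) n <- n + max(0L, sum(u == p) - sum(v == p))
      n
    }
    max(oneWay(pa, pb), oneWay(pb, pa))
  }
  d <- adjacencyDistance(ago, ltpf)
  expect_gt(d, 0L)
  expect_equal(d, naive(ago, ltpf))
  set.seed(9)
  for (i in 1:5) {
    rt <- applyRandomTDRL(ago, 2L, seed = i)
    expect_equal(adjacencyDistance(ago, rt$order), naive(ago, rt$order))
  }
})
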