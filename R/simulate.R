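# Synthetic annotated mitogenome generator. Emits circular genomes with
# realistic anuran-style gene complements and sizes, codon usage with a
# tunable link between a tRNA's distance from the control region and
# usage of the codons it decodes, pseudogene relics, TDRL-derived gene
# orders, and congeneric partner genomes evolved to target dS/dN.
# Every true parameter (codon counts, distances, substitution counts,
# rearrangement events) is recorded in a ledger so downstream
# statistics can be checked against ground truth.

.DEFAULT_GENE_CODONS <- c(
  nad1 = 322, nad2 = 344, cox1 = 516, cox2 = 230, atp8 = 55, atp6 = 227,
  cox3 = 261, nad3 = 115, nad4L = 98, nad4 = 459, nad5 = 605,
  nad6 = 172, cob = 380)

.DEFAULT_RRNA_BP <- c(rrnS = 930, rrnL = 1580)

#' Simulation specification
#'
#' Builds the parameter list consumed by [generateGenome()] and
#' [generateCorrelatedSet()]. Defaults emulate anuran mitogenomes:
#' circular ~16-17 kb genomes with 13 protein-coding genes (codon
#' counts near anuran values, e.g. cox1 = 516 codons), 2 rRNAs, 22
#' tRNAs of 68-73 bp, a repeat-bearing control region and a ~30 bp OL.
#'
#' @param seed master seed; all randomness derives from it.
#' @param nSpecies number of genomes.
#' @param orders reference order name(s) (`"vertebrate_AGO"` or
#'   `"neobatrachian_LTPF"`), recycled across species.
#' @param tdrlEvents number of random TDRL events layered on each
#'   species' reference order, recycled (default 0).
#' @param geneCodons named vector of protein-gene codon counts.
#' @param rrnaBp named vector of rRNA lengths (bp).
#' @param trnaBp range of tRNA gene lengths (bp).
#' @param crFlank,crUnit,crCopies control-region composition: random
#'   flank plus a tandem repeat of `crUnit` bp repeated `crCopies`
#'   times.
#' @param olBp length of the light-strand replication origin.
#' @param usageAlpha within-family Dirichlet concentration of the codon
#'   usage model (larger = less within-family codon bias noise).
#' @param usageAlphaFam family-level Dirichlet concentration: each
#'   species draws its 22 codon-family weights from a symmetric
#'   Dirichlet, modelling species-specific codon bias; smaller values
#'   give noisier bias and weaker realized distance-usage correlations
#'   at a given beta.
#' @param beta distance-link coefficient (per kb): a codon family's
#'   usage weight is proportional to `exp(-beta * distance_kb)` of its
#'   tRNA, so beta > 0 makes codons of CR-proximal tRNAs more used.
#' @param pseudogenize tRNA tokens to pseudogenize into short relics
#'   (e.g. `"trnS(AGY)"`).
#' @param relicBp length of a pseudogene relic (default 62 bp).
#' @param pairDS,pairDN target dS and dN for congeneric partner
#'   generation via [evolvePair()].
#' @param idPrefix genome id prefix.
#' @return a list of class `SimSpec`.
#' @export
simSpec <- function(seed = 1L, nSpecies = 1L,
                    orders = "vertebrate_AGO", tdrlEvents = 0L,
                    geneCodons = .DEFAULT_GENE_CODONS,
                    rrnaBp = .DEFAULT_RRNA_BP, trnaBp = 68:73,
                    crFlank = 300L, crUnit = 60L, crCopies = 12L,
                    olBp = 30L, usageAlpha = 10, usageAlphaFam = 60,
                    beta = 0,
                    pseudogenize = character(0), relicBp = 62L,
                    pairDS = NULL, pairDN = NULL, idPrefix = "SIM") {
  spec <- list(seed = as.integer(seed), nSpecies = as.integer(nSpecies),
               orders = orders, tdrlEvents = tdrlEvents,
               geneCodons = geneCodons, rrnaBp = rrnaBp, trnaBp = trnaBp,
               crFlank = crFlank, crUnit = crUnit, crCopies = crCopies,
               olBp = olBp, usageAlpha = usageAlpha,
               usageAlphaFam = usageAlphaFam, beta = beta,
               pseudogenize = pseudogenize, relicBp = relicBp,
               pairDS = pairDS, pairDN = pairDN, idPrefix = idPrefix)
  class(spec) <- "SimSpec"
  spec
}

.randSeq <- function(n) paste(sample(.NT, n, replace = TRUE),
                              collapse = "")

.rdirichlet <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# Lay out the features of one order; returns the feature table (with
# lengths resolved) but no sequences yet.
.layoutFeatures <- function(order, spec) {
  tk <- order@tokens
  trnaSet <- trnaTokens()
  rows <- list()
  pos <- 0L
  for (i in seq_len(nrow(tk))) {
    nm <- tk$name[i]
    if (tk$pseudo[i]) {
      len <- spec$relicBp
      kind <- if (nm %in% trnaSet) "tRNA" else "noncoding"
    } else if (nm %in% trnaSet) {
      len <- sample(spec$trnaBp, 1L)
      kind <- "tRNA"
    } else if (nm %in% names(spec$geneCodons)) {
      len <- 3L * (spec$geneCodons[[nm]] + 1L) # incl. stop codon
      kind <- "CDS"
    } else if (nm %in% names(spec$rrnaBp)) {
      len <- spec$rrnaBp[[nm]]
      kind <- "rRNA"
    } else if (nm == "OL") {
      len <- spec$olBp
      kind <- "OL"
    } else if (nm == "CR") {
      len <- spec$crFlank + spec$crUnit * spec$crCopies
      kind <- "CR"
    } else { # spacer or unknown
      len <- 100L
      kind <- "noncoding"
    }
    rows[[i]] <- data.frame(
      name = nm, kind = kind, strand = tk$strand[i], start = pos,
      end = pos + as.integer(len), pseudo = tk$pseudo[i],
      anticodon = if (kind == "tRNA" && !tk$pseudo[i])
        .TRNA_ANTICODON[[nm]] else NA_character_,
      stringsAsFactors = FALSE)
    pos <- pos + as.integer(len)
  }
  list(features = do.call(rbind, rows), length = pos)
}

# Codon sampling probabilities for one species given its tRNA distances.
# Family usage = species-level Dirichlet draw (codon-bias noise) times
# the distance link exp(-beta * d_kb); codons split within a family by
# a second Dirichlet draw. Family weights are size-free, so at beta = 0
# every tRNA has the same expected usage and the null distance-usage
# correlation is clean.
.codonProbs <- function(distances, spec) {
  map <- trnaCodonMap()
  L2 <- if (length(distances)) max(distances) else 1
  famBase <- setNames(
    .rdirichlet(rep(spec$usageAlphaFam, length(map))), names(map))
  probs <- setNames(numeric(0), character(0))
  for (tok in names(map)) {
    codons <- map[[tok]]
    w <- .rdirichlet(rep(spec$usageAlpha, length(codons)))
    d <- if (tok %in% names(distances)) distances[[tok]] else L2 / 2
    probs[codons] <- w * famBase[tok] * exp(-spec$beta * d / 1000)
  }
  probs / sum(probs)
}

#' Generate one synthetic annotated mitogenome
#'
#' Builds the genome for species `i` of a [simSpec()]: the requested
#' gene order (reference order, optionally rearranged by random TDRL
#' events), CDS sequences drawn codon by codon from the species' codon
#' usage model (60 sense codons only, so no in-frame stops, each CDS
#' terminated by TAA), tRNA placeholders of 68-73 bp with the canonical
#' anticodon, rRNA placeholders, a repeat-bearing CR and a short OL.
#' Requested tRNAs are pseudogenized into short relics. The ledger
#' records the true codon counts (per gene and pooled), the true tRNA
#' distances from the CR, the codon sampling probabilities and any
#' TDRL events applied. Output is fully determined by
#' `(spec$seed, i)`.
#'
#' @param spec a [simSpec()] object.
#' @param i species index (1-based).
#' @return list with elements `genome` ([MitoGenome-class]) and
#'   `ledger`.
#' @export
generateGenome <- function(spec, i = 1L) {
  set.seed(.subSeed(spec$seed, i))
  recycle <- function(x) x[((i - 1L) %% length(x)) + 1L]
  refName <- recycle(spec$orders)
  order <- referenceOrder(refName)
  k <- recycle(spec$tdrlEvents)
  events <- list()
  if (k > 0L) {
    rt <- applyRandomTDRL(order, k, seed = .subSeed(spec$seed, i + 500000L))
    order <- rt$order
    events <- rt$scenarios
  }
  if (length(spec$pseudogenize)) {
    tk <- order@tokens
    tk$pseudo[tk$name %in% spec$pseudogenize] <- TRUE
    order <- newGeneOrder(tk[, c("name", "strand", "pseudo")])
  }
  if (spec$beta != 0 && !"CR" %in% order@tokens$name)
    stop("distance-linked usage (beta != 0) requires a CR in the order")
  lay <- .layoutFeatures(order, spec)
  f <- lay$features
  L <- lay$length
  # true tRNA distances: CR 3' end is position L == 0 by construction
  crEnd <- .modLen(f$end[f$kind == "CR"][1], L)
  tr <- f[f$kind == "tRNA" & !f$pseudo, , drop = FALSE]
  fiveP <- ifelse(tr$strand == "+", tr$start, .modLen(tr$end - 1L, L))
  dAll <- .modLen(fiveP - crEnd, L)
  ordd <- order(dAll)
  firstCopy <- !duplicated(tr$name[ordd])
  distances <- setNames(dAll[ordd][firstCopy], tr$name[ordd][firstCopy])
  probs <- .codonProbs(distances, spec)
  sense <- names(probs)
  perGeneCounts <- list()
  seqs <- character(nrow(f))
  for (j in seq_len(nrow(f))) {
    len <- f$end[j] - f$start[j]
    if (f$kind[j] == "CDS" && !f$pseudo[j]) {
      nCod <- len %/% 3L - 1L
      codons <- sample(sense, nCod, replace = TRUE, prob = probs)
      cnt <- table(factor(codons, levels = sense))
      perGeneCounts[[f$name[j]]] <- setNames(as.numeric(cnt), sense)
      coding <- paste0(paste(codons, collapse = ""), "TAA")
      seqs[j] <- if (f$strand[j] == "-") .revcomp(coding) else coding
    } else if (f$kind[j] == "CR") {
      unit <- .randSeq(spec$crUnit)
      seqs[j] <- paste0(.randSeq(spec$crFlank),
                        paste(rep(unit, spec$crCopies), collapse = ""))
    } else {
      seqs[j] <- .randSeq(len)
    }
  }
  pooled <- Reduce(`+`, perGeneCounts,
                   init = setNames(numeric(length(sense)), sense))
  genome <- newMitoGenome(
    sprintf("%s%03d", spec$idPrefix, i), L, f,
    sequence = paste(seqs, collapse = ""))
  ledger <- list(
    species = genome@id, order = orderTokenStrings(order),
    reference = refName, tdrlEvents = events,
    trueDistances = distances, codonProbs = probs,
    trueCodonCounts = perGeneCounts, truePooled = pooled)
  list(genome = genome, ledger = ledger)
}

#' Generate a set of genomes with distance-linked codon usage
#'
#' Generates `spec$nSpecies` genomes whose per-species codon usage
#' weights are linked to that species' true tRNA distances through
#' `spec$beta`, then records in the ledger the realized pooled Pearson
#' and Spearman correlations computed from the true codon counts and
#' true distances (the same points and formulas the pipeline uses, so
#' pipeline recomputation must agree to numerical precision).
#'
#' @param spec a [simSpec()] object.
#' @return list with `genomes` (list of [MitoGenome-class]) and
#'   `ledger` (per-species ledgers plus `records` and `realized`).
#' @export
generateCorrelatedSet <- function(spec) {
  gens <- lapply(seq_len(spec$nSpecies), function(i)
    generateGenome(spec, i))
  genomes <- lapply(gens, `[[`, "genome")
  ledgers <- lapply(gens, `[[`, "ledger")
  map <- trnaCodonMap()
  recs <- do.call(rbind, lapply(ledgers, function(le) {
    trna <- names(le$trueDistances)
    usage <- vapply(map[trna], function(cdn) sum(le$truePooled[cdn]),
                    numeric(1))
    data.frame(species = le$species, trna = trna,
               distance = unname(le$trueDistances),
               usage = unname(usage), stringsAsFactors = FALSE)
  }))
  rownames(recs) <- NULL
  realized <- list(
    pearson = cor(recs$distance, recs$usage, method = "pearson"),
    spearman = cor(recs$distance, recs$usage, method = "spearman"),
    n = nrow(recs))
  list(genomes = genomes,
       ledger = list(species = ledgers, records = recs,
                     realized = realized))
}

#' Calibrate the distance-link coefficient for a target correlation
#'
#' Coarse search over a beta grid: for each candidate the set is
#' simulated once and the realized pooled Spearman correlation
#' recorded; the beta whose realized value is closest to the target is
#' returned. Count data cannot hit a target correlation exactly, so
#' the realized value is reported rather than promised.
#'
#' @param spec a [simSpec()] object (its `beta` is ignored).
#' @param targetRho target pooled Spearman correlation (negative for
#'   CR-proximal enrichment).
#' @param betaGrid candidate values of beta (per kb).
#' @return list with `beta` and `realizedRho`.
#' @export
calibrateBeta <- function(spec, targetRho,
                          betaGrid = c(0.01, 0.02, 0.03, 0.05, 0.08,
                                       0.12, 0.2, 0.35, 0.6)) {
  best <- NULL
  for (b in betaGrid) {
    sp <- spec
    sp$beta <- b
    rho <- generateCorrelatedSet(sp)$ledger$realized$spearman
    if (is.null(best) || abs(rho - targetRho) < abs(best$realizedRho -
                                                    targetRho))
      best <- list(beta = b, realizedRho = rho)
  }
  best
}

# Per-codon mutation menus: synonymous changes, and nonsynonymous
# changes that do not create a stop codon.
.mutationMenus <- function() {
  if (!is.null(.pkgCache$mutMenu)) return(.pkgCache$mutMenu)
  code <- mitoGeneticCode()
  sense <- mitoSenseCodons()
  syn <- list()
  nonsyn <- list()
  for (cdn in sense) {
    s <- list()
    ns <- list()
    for (pos in 1:3) for (nt in setdiff(.NT, substr(cdn, pos, pos))) {
      alt <- cdn
      substr(alt, pos, pos) <- nt
      if (code[[alt]] == "*") next
      if (code[[alt]] == code[[cdn]]) s[[length(s) + 1L]] <- alt
      else ns[[length(ns) + 1L]] <- alt
    }
    syn[[cdn]] <- unlist(s) %||% character(0)
    nonsyn[[cdn]] <- unlist(ns) %||% character(0)
  }
  .pkgCache$mutMenu <- list(syn = syn, nonsyn = nonsyn)
  .pkgCache$mutMenu
}

.mutateCodons <- function(codons, nEvents, menuName) {
  menus <- .mutationMenus()[[menuName]]
  counts <- lengths(menus)[codons]
  applied <- 0L
  for (e in seq_len(nEvents)) {
    if (all(counts == 0)) break
    k <- sample.int(length(codons), 1L, prob = counts)
    opts <- menus[[codons[k]]]
    codons[k] <- opts[sample.int(length(opts), 1L)]
    counts[k] <- length(menus[[codons[k]]])
    applied <- applied + 1L
  }
  list(codons = codons, applied = applied)
}

#' Evolve a congeneric partner genome to target dS and dN
#'
#' For each protein-coding gene, draws Poisson numbers of synonymous
#' and nonsynonymous single-nucleotide substitutions calibrated so the
#' expected NG86 dS and dN equal the targets (the Jukes-Cantor map is
#' inverted to get target proportions pS and pN, and the expected
#' event counts are pS x S and pN x N sites). Substitutions are placed
#' uniformly over the currently available changes of the requested
#' class and never create stop codons. The ledger records the realized
#' applied counts per gene, together with each gene's site counts.
#'
#' @param genome a [MitoGenome-class] object with a sequence.
#' @param targetDS,targetDN target synonymous/nonsynonymous distances
#'   (must map to proportions < 3/4).
#' @param seed RNG seed for the substitution process.
#' @return list with `genome` (the partner, id suffixed `_p`) and
#'   `ledger` (data.frame: gene, S, N, synApplied, nonsynApplied).
#' @export
evolvePair <- function(genome, targetDS, targetDN, seed = 1L) {
  if (is.na(genome@sequence)) stop("genome has no sequence")
  if (targetDS < 0 || targetDN < 0) stop("targets must be non-negative")
  pSt <- (3 / 4) * (1 - exp(-4 * targetDS / 3))
  pNt <- (3 / 4) * (1 - exp(-4 * targetDN / 3))
  if (pSt >= 3 / 4 || pNt >= 3 / 4)
    stop("unreachable targets: proportion at or above saturation (3/4)")
  set.seed(seed)
  f <- genome@features
  cds <- f[f$kind == "CDS" & !f$pseudo, , drop = FALSE]
  seqChars <- strsplit(genome@sequence, "")[[1]]
  siteTab <- .ng86Sites()
  stops <- mitoStopCodons()
  led <- list()
  L <- genome@length
  for (i in seq_len(nrow(cds))) {
    nt <- .circSubstr(genome@sequence, cds$start[i], cds$end[i], L)
    if (cds$strand[i] == "-") nt <- .revcomp(nt)
    codons <- .codonSplit(nt)
    tailStop <- length(codons) && codons[length(codons)] %in% stops
    body <- if (tailStop) codons[-length(codons)] else codons
    if (any(!body %in% names(siteTab)))
      stop("gene ", cds$name[i], " contains stop/ambiguous codons")
    S <- sum(siteTab[body])
    N <- 3 * length(body) - S
    nS <- rpois(1L, pSt * S)
    nN <- rpois(1L, pNt * N)
    ms <- .mutateCodons(body, nS, "syn")
    mn <- .mutateCodons(ms$codons, nN, "nonsyn")
    mutated <- paste0(paste(mn$codons, collapse = ""),
                      if (tailStop) codons[length(codons)] else "")
    if (cds$strand[i] == "-") mutated <- .revcomp(mutated)
    flen <- .featLength(cds$start[i], cds$end[i], L)
    posIdx <- .modLen(cds$start[i] + seq_len(flen) - 1L, L) + 1L
    seqChars[posIdx] <- strsplit(mutated, "")[[1]]
    led[[i]] <- data.frame(gene = cds$name[i], S = S, N = N,
                           synApplied = ms$applied,
                           nonsynApplied = mn$applied,
                           stringsAsFactors = FALSE)
  }
  partner <- newMitoGenome(paste0(genome@id, "_p"), L, f,
                           sequence = paste(seqChars, collapse = ""),
                           circular = genome@circular)
  list(genome = partner, ledger = do.call(rbind, led))
}

#' Apply random TDRL events to a gene order
#'
#' Draws `k` sequential random single-TDRL events (random contiguous
#' tract, random fates with exactly one copy of each token retained and
#' non-retained copies pseudogenized or deleted) and records each
#' scenario. Identity events (derived equal to the input) are
#' rejected and resampled, so any `k >= 1` yields a rearranged order.
#'
#' @param order a [GeneOrder-class] object.
#' @param k number of events (k = 0 returns the order unchanged).
#' @param seed RNG seed.
#' @param maxTract maximum tract length in genes (default 4).
#' @return list with `order` (the derived [GeneOrder-class]) and
#'   `scenarios` (list of [TDRLScenario-class]).
#' @export
applyRandomTDRL <- function(order, k, seed = 1L, maxTract = 4L) {
  set.seed(seed)
  tokens <- orderTokenStrings(order)
  scenarios <- list()
  for (e in seq_len(k)) {
    for (try in 1:100) {
      n <- length(tokens)
      m <- sample.int(min(maxTract, n - 1L), 1L)
      i <- sample.int(n - m + 1L, 1L)
      tract <- tokens[i:(i + m - 1L)]
      retained <- sample(c(1L, 2L), m, replace = TRUE)
      other <- ifelse(.isPseudoTok(tract), "deleted",
                      sample(c("pseudogenized", "deleted"), m,
                             replace = TRUE, prob = c(0.4, 0.6)))
      fate1 <- ifelse(retained == 1L, "retained", other)
      fate2 <- ifelse(retained == 2L, "retained", other)
      sc <- newTDRLScenario(.stripPrime(tract), i, i + m - 1L, fate1,
                            fate2)
      derived <- applyTDRL(tokens, sc)
      if (!identical(derived, tokens)) break
    }
    tokens <- derived
    scenarios[[e]] <- sc
  }
  list(order = newGeneOrder(tokens), scenarios = scenarios)
}
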