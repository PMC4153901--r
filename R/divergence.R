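# Pairwise synonymous/nonsynonymous divergence: the Nei-Gojobori (1986)
# counting estimator under the vertebrate mitochondrial code, with
# equal pathway weighting for multi-difference codons and Jukes-Cantor
# distance correction. Changes creating a stop codon count as
# nonsynonymous in site counts; mutation pathways passing through a
# stop codon are excluded from averaging (all pathways are used as a
# fallback when every path is blocked).

.NT <- c("A", "C", "G", "T")

# Per-codon synonymous site count (sum over the three positions of the
# fraction of the three possible changes that are synonymous).
.ng86Sites <- function() {
  if (!is.null(.pkgCache$ngSites)) return(.pkgCache$ngSites)
  code <- mitoGeneticCode()
  sense <- mitoSenseCodons()
  s <- setNames(numeric(length(sense)), sense)
  for (cdn in sense) {
    aa <- code[[cdn]]
    syn <- 0
    for (pos in 1:3) {
      for (nt in setdiff(.NT, substr(cdn, pos, pos))) {
        alt <- cdn
        substr(alt, pos, pos) <- nt
        if (code[[alt]] == aa) syn <- syn + 1 # change to stop: nonsyn
      }
    }
    s[cdn] <- syn / 3
  }
  .pkgCache$ngSites <- s
  s
}

# Pathway-averaged synonymous/nonsynonymous difference counts for one
# codon pair; memoized over all sense-codon pairs.
.ng86DiffOne <- function(a, b) {
  code <- mitoGeneticCode()
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (!length(pos)) return(c(0, 0))
  paths <- if (length(pos) == 1L) list(pos) else
    asplit(.permutations(pos), 1L)
  tally <- function(ord, allowStops) {
    cur <- a
    sd <- 0
    nd <- 0
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (!allowStops && code[[nxt]] == "*") return(NULL)
      if (code[[nxt]] == code[[cur]] && code[[nxt]] != "*")
        sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- Filter(Negate(is.null), lapply(paths, tally, allowStops = FALSE))
  if (!length(res)) res <- lapply(paths, tally, allowStops = TRUE)
  Reduce(`+`, res) / length(res)
}

.permutations <- function(x) {
  if (length(x) == 1L) return(matrix(x, 1L))
  out <- NULL
  for (i in seq_along(x))
    out <- rbind(out, cbind(x[i], .permutations(x[-i])))
  out
}

.ng86DiffTable <- function() {
  if (!is.null(.pkgCache$ngDiff)) return(.pkgCache$ngDiff)
  sense <- mitoSenseCodons()
  n <- length(sense)
  sd <- matrix(0, n, n, dimnames = list(sense, sense))
  nd <- sd
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- .ng86DiffOne(sense[i], sense[j])
      sd[i, j] <- d[1]
      nd[i, j] <- d[2]
    }
  }
  .pkgCache$ngDiff <- list(sd = sd, nd = nd)
  .pkgCache$ngDiff
}

.jc <- function(p) -(3 / 4) * log(1 - (4 / 3) * p)

#' Nei-Gojobori (1986) pairwise divergence of two coding sequences
#'
#' Computes average synonymous/nonsynonymous site counts (S, N),
#' pathway-averaged difference counts (Sd, Nd), proportions
#' pS = Sd/S and pN = Nd/N, and Jukes-Cantor-corrected distances
#' dS and dN, under the vertebrate mitochondrial code. omega = dN/dS,
#' with a flag (`"dS=0"` or `"0/0"`) when dS is zero. Codons containing
#' gaps or ambiguity characters in either sequence are skipped in
#' pairs; a terminal stop codon (in either sequence) is trimmed.
#'
#' @param cdsA,cdsB aligned coding sequences of equal length (DNA
#'   strings); incomplete terminal codons are trimmed.
#' @param gene optional gene name used in error messages.
#' @return one-row data.frame with columns `gene`, `codons`, `S_sites`,
#'   `N_sites`, `Sd`, `Nd`, `pS`, `pN`, `dS`, `dN`, `omega`,
#'   `omega_flag`.
#' @export
ng86Pairwise <- function(cdsA, cdsB, gene = NA_character_) {
  a <- toupper(as.character(cdsA))
  b <- toupper(as.character(cdsB))
  if (nchar(a) != nchar(b))
    stop(sprintf("length mismatch%s: %d vs %d nt",
                 if (is.na(gene)) "" else paste0(" in ", gene),
                 nchar(a), nchar(b)))
  ca <- .codonSplit(a)
  cb <- .codonSplit(b)
  stops <- mitoStopCodons()
  nc <- length(ca)
  if (nc && (ca[nc] %in% stops || cb[nc] %in% stops)) {
    ca <- ca[-nc]
    cb <- cb[-nc]
  }
  ok <- .isDNA(ca) & .isDNA(cb)
  ca <- ca[ok]
  cb <- cb[ok]
  if (any(ca %in% stops) || any(cb %in% stops))
    stop(sprintf("internal stop codon%s; likely pseudogene or frameshift",
                 if (is.na(gene)) "" else paste0(" in ", gene)))
  if (!length(ca)) stop("no comparable codons")
  siteTab <- .ng86Sites()
  S <- (sum(siteTab[ca]) + sum(siteTab[cb])) / 2
  N <- 3 * length(ca) - S
  dt <- .ng86DiffTable()
  idx <- cbind(match(ca, rownames(dt$sd)), match(cb, colnames(dt$sd)))
  Sd <- sum(dt$sd[idx])
  Nd <- sum(dt$nd[idx])
  pS <- Sd / S
  pN <- Nd / N
  if (pS >= 3 / 4 || pN >= 3 / 4)
    stop(sprintf("substitution saturation (p >= 3/4)%s",
                 if (is.na(gene)) "" else paste0(" in gene ", gene)))
  dS <- .jc(pS)
  dN <- .jc(pN)
  flag <- if (dS == 0 && dN == 0) "0/0"
          else if (dS == 0) "dS=0" else "ok"
  data.frame(gene = gene, codons = length(ca), S_sites = S, N_sites = N,
             Sd = Sd, Nd = Nd, pS = pS, pN = pN, dS = dS, dN = dN,
             omega = if (flag == "ok") dN / dS else NA_real_,
             omega_flag = flag, stringsAsFactors = FALSE)
}

.cdsSequence <- function(genome, row) {
  nt <- .circSubstr(genome@sequence, row$start, row$end, genome@length)
  if (row$strand == "-") nt <- .revcomp(nt)
  nt
}

#' Per-gene divergence between two genomes
#'
#' Pairs protein-coding genes by normalized name and runs
#' [ng86Pairwise()] on each shared gene. No alignment is performed:
#' gene sequences must be length-matched (true by construction for
#' simulated congeneric pairs; real data require pre-aligned input);
#' length-mismatched genes are skipped with a message.
#'
#' @param a,b [MitoGenome-class] objects with sequences and CDS
#'   annotations.
#' @return data.frame, one row per compared gene (see
#'   [ng86Pairwise()]), with a `pair` column.
#' @export
genomePairDivergence <- function(a, b) {
  fa <- a@features
  fb <- b@features
  ca <- fa[fa$kind == "CDS" & !fa$pseudo & fa$copy == 1L, , drop = FALSE]
  cb <- fb[fb$kind == "CDS" & !fb$pseudo & fb$copy == 1L, , drop = FALSE]
  shared <- intersect(ca$name, cb$name)
  if (!length(shared))
    stop(sprintf("no shared protein-coding genes between '%s' and '%s'",
                 a@id, b@id))
  pairId <- paste(a@id, b@id, sep = "~")
  rows <- list()
  for (g in shared) {
    sa <- .cdsSequence(a, ca[ca$name == g, ][1L, ])
    sb <- .cdsSequence(b, cb[cb$name == g, ][1L, ])
    res <- tryCatch(ng86Pairwise(sa, sb, gene = g), error = function(e) {
      message(sprintf("skipping gene %s in pair %s: %s", g, pairId,
                      conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  if (!length(rows)) stop("no comparable genes in pair ", pairId)
  out <- do.call(rbind, rows)
  out <- cbind(pair = pairId, out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Compare divergence values between two groups
#'
#' Two-sided Mann-Whitney U test by default (no normality assumption);
#' Welch's t test optional. The statistic reported for the default
#' method is the U statistic.
#'
#' @param groupA,groupB numeric vectors of per-gene rates (each with at
#'   least 2 finite values).
#' @param method `"wilcox"` (default) or `"welch"`.
#' @return list with `statistic`, `p`, `method`.
#' @export
compareRateGroups <- function(groupA, groupB,
                              method = c("wilcox", "welch")) {
  method <- match.arg(method)
  groupA <- groupA[is.finite(groupA)]
  groupB <- groupB[is.finite(groupB)]
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs at least 2 finite values")
  if (method == "wilcox") {
    ht <- suppressWarnings(
      wilcox.test(groupA, groupB, exact = FALSE, correct = FALSE))
    list(statistic = unname(ht$statistic), p = ht$p.value,
         method = "Mann-Whitney U (two-sided, normal approximation)")
  } else {
    ht <- stats::t.test(groupA, groupB)
    list(statistic = unname(ht$statistic), p = ht$p.value,
         method = "Welch two-sample t (two-sided)")
  }
}
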