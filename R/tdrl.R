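# Tandem duplication-random loss (TDRL) scenario inference. A single
# TDRL event duplicates a contiguous tract of genes in tandem; each
# gene's two copies are then assigned fates (exactly one retained, the
# other pseudogenized or deleted). inferTDRL() finds all minimal-cost
# single-event scenarios transforming an ancestral segment into an
# observed derived segment; applyTDRL() is the forward model.
#
# Segments are linear token vectors in the package dialect: plain gene
# names, with a trailing "'" marking pseudogenes.

.stripPrime <- function(x) sub("'$", "", x)
.isPseudoTok <- function(x) grepl("'$", x)

.segTokens <- function(x) {
  if (is(x, "GeneOrder")) orderTokenStrings(x) else as.character(x)
}

#' Construct a TDRL scenario
#'
#' @param genes gene names of the duplicated tract, in ancestral order.
#' @param from,to 1-based bounds of the tract in the ancestral segment.
#' @param fate1,fate2 per-gene fates of the left and right tandem copy
#'   (`"retained"`, `"pseudogenized"`, `"deleted"`); exactly one copy of
#'   each gene must be retained.
#' @return a [TDRLScenario-class] object.
#' @export
newTDRLScenario <- function(genes, from, to, fate1, fate2) {
  new("TDRLScenario", genes = as.character(genes),
      from = as.integer(from), to = as.integer(to),
      fate1 = as.character(fate1), fate2 = as.character(fate2),
      cost = c(length(genes),
               sum(fate1 != "retained") + sum(fate2 != "retained")))
}

.renderCopy <- function(tokens, fates) {
  out <- character(0)
  for (i in seq_along(tokens)) {
    out <- c(out, switch(fates[i],
      retained = tokens[i],
      pseudogenized = paste0(.stripPrime(tokens[i]), "'"),
      deleted = character(0),
      stop("fate table incomplete or invalid: ", fates[i])))
  }
  out
}

#' Apply a TDRL scenario to a gene-order segment
#'
#' Inserts the tandem duplicate immediately after the original tract and
#' applies the per-copy fates. Deleted copies leave no token; a
#' pseudogenized copy leaves the gene's token flagged with `'`.
#' Deterministic.
#'
#' @param segment character vector of segment tokens (or a
#'   [GeneOrder-class], rendered via [orderTokenStrings()]).
#' @param scenario a [TDRLScenario-class] object.
#' @return character vector: the derived segment tokens.
#' @export
applyTDRL <- function(segment, scenario) {
  seg <- .segTokens(segment)
  i <- scenario@from
  j <- scenario@to
  if (i < 1L || j > length(seg) || i > j)
    stop("duplication interval invalid for this segment")
  tract <- seg[i:j]
  if (!identical(.stripPrime(tract), scenario@genes))
    stop("scenario genes do not match the segment tract")
  if (length(scenario@fate1) != length(tract) ||
      length(scenario@fate2) != length(tract))
    stop("fate table incomplete")
  c(if (i > 1L) seg[seq_len(i - 1L)] else character(0),
    .renderCopy(tract, scenario@fate1),
    .renderCopy(tract, scenario@fate2),
    if (j < length(seg)) seg[(j + 1L):length(seg)] else character(0))
}

# Check that `part` (a token vector) is an in-order selection of
# distinct genes from `blockNames`; return the matched indices or NULL.
.matchSubseq <- function(part, blockNames) {
  if (!length(part)) return(integer(0))
  nm <- .stripPrime(part)
  if (anyDuplicated(nm)) return(NULL)
  idx <- match(nm, blockNames)
  if (anyNA(idx)) return(NULL)
  if (is.unsorted(idx, strictly = TRUE)) return(NULL)
  idx
}

#' Infer single-TDRL scenarios explaining a derived gene-order segment
#'
#' Searches all contiguous duplication intervals of the ancestral
#' segment and all fate assignments for single tandem
#' duplication-random loss events whose application reproduces the
#' derived segment exactly (names, order, pseudogene flags). Returns
#' all scenarios of minimal cost, where cost is compared
#' lexicographically: fewest duplicated genes first, then fewest
#' non-retained copies. Ties are all reported, ordered by leftmost
#' duplication interval.
#'
#' A derived segment identical to the ancestral one yields an empty
#' list (no event needed); a derived segment that no single TDRL event
#' can produce also yields an empty list. A gene name appearing in the
#' derived segment but absent from the ancestral one is an
#' inconsistency and raises an error.
#'
#' @param ancestral,derived segment token vectors (trailing `'` marks
#'   pseudogenes) or [GeneOrder-class] objects. Ancestral gene names
#'   must be unique and functional.
#' @param maxSegment exhaustive-search bound on the ancestral segment
#'   length (default 12).
#' @return list of [TDRLScenario-class] objects (possibly empty).
#' @export
inferTDRL <- function(ancestral, derived, maxSegment = 12L) {
  anc <- .segTokens(ancestral)
  der <- .segTokens(derived)
  if (length(anc) > maxSegment)
    stop(sprintf(
      "ancestral segment has %d genes, above the exhaustive-search bound (%d); raise maxSegment to search anyway",
      length(anc), maxSegment))
  if (any(.isPseudoTok(anc)))
    stop("ancestral segment must contain functional genes only")
  if (anyDuplicated(anc))
    stop("ancestral segment gene names must be unique")
  derNames <- .stripPrime(der)
  if (!all(derNames %in% anc))
    stop("inconsistency: gene(s) in derived absent from ancestral: ",
         paste(unique(derNames[!derNames %in% anc]), collapse = ", "))
  if (identical(anc, der)) return(list())
  derFun <- der[!.isPseudoTok(der)]
  # single TDRL retains every ancestral gene exactly once
  if (length(derFun) != length(anc) || !setequal(derFun, anc) ||
      anyDuplicated(derFun))
    return(list())
  n <- length(anc)
  nd <- length(der)
  found <- list()
  for (i in seq_len(n)) {
    if (i > 1L && !identical(der[seq_len(i - 1L)], anc[seq_len(i - 1L)]))
      next
    for (j in i:n) {
      tailLen <- n - j
      if (tailLen > 0L) {
        if (nd - tailLen < i - 1L) next
        if (!identical(der[(nd - tailLen + 1L):nd], anc[(j + 1L):n]))
          next
      }
      mid <- if (nd - tailLen >= i) der[i:(nd - tailLen)] else character(0)
      block <- anc[i:j]
      m <- length(block)
      for (s in 0:length(mid)) {
        part1 <- if (s >= 1L) mid[seq_len(s)] else character(0)
        part2 <- if (s < length(mid)) mid[(s + 1L):length(mid)]
                 else character(0)
        idx1 <- .matchSubseq(part1, block)
        if (is.null(idx1)) next
        idx2 <- .matchSubseq(part2, block)
        if (is.null(idx2)) next
        fate1 <- rep("deleted", m)
        fate2 <- rep("deleted", m)
        fate1[idx1] <- ifelse(.isPseudoTok(part1), "pseudogenized",
                              "retained")
        fate2[idx2] <- ifelse(.isPseudoTok(part2), "pseudogenized",
                              "retained")
        if (!all(xor(fate1 == "retained", fate2 == "retained"))) next
        found[[length(found) + 1L]] <-
          newTDRLScenario(block, i, j, fate1, fate2)
      }
    }
  }
  if (!length(found)) return(list())
  costs <- t(vapply(found, function(sc) sc@cost, integer(2)))
  ord <- order(costs[, 1L], costs[, 2L],
               vapply(found, function(sc) sc@from, integer(1)))
  found <- found[ord]
  costs <- costs[ord, , drop = FALSE]
  keep <- costs[, 1L] == costs[1L, 1L] & costs[, 2L] == costs[1L, 2L]
  found[keep]
}

# Canonical string form used for scenario set comparison in tests.
.scenarioKey <- function(sc) {
  paste(sc@from, sc@to, paste(sc@genes, collapse = ","),
        paste(substr(sc@fate1, 1, 1), collapse = ""),
        paste(substr(sc@fate2, 1, 1), collapse = ""), sep = "|")
}
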