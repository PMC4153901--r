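#' @import methods
#' @importFrom stats cor cor.test chisq.test wilcox.test rgamma rpois runif setNames
#' @importFrom utils read.delim write.table head tail
NULL

.GENE_KINDS <- c("CDS", "tRNA", "rRNA", "CR", "OL", "noncoding")

#' MitoGenome: an annotated circular mitochondrial genome
#'
#' Container for one mitochondrial genome: its length, circular topology,
#' optional nucleotide sequence, and an ordered feature table.
#'
#' Coordinates are 0-based half-open on the genome circle. A feature may
#' wrap the numbering origin, in which case `start > end` and `end` is
#' interpreted modulo the genome length. Feature length is
#' `(end - start) mod length` and must be positive.
#'
#' The feature table has columns:
#' \describe{
#'   \item{name}{normalized gene token (MitoZoa-style: `cox1`, `nad5`,
#'     `trnL(CUN)`, `rrnS`, `CR`, `OL`, `spacer`, ...)}
#'   \item{kind}{one of `CDS`, `tRNA`, `rRNA`, `CR`, `OL`, `noncoding`}
#'   \item{strand}{`+` (heavy strand, annotation direction) or `-`}
#'   \item{start,end}{0-based half-open coordinates}
#'   \item{pseudo}{logical pseudogene flag}
#'   \item{copy}{copy index, consecutive from 1 per name in scan order}
#'   \item{anticodon}{3-letter anticodon for tRNAs, `NA` otherwise}
#' }
#'
#' @slot id accession-like identifier.
#' @slot length genome length in bp.
#' @slot circular logical topology flag.
#' @slot sequence nucleotide string of length `length`, or `NA` if absent.
#' @slot features data.frame as described above, sorted by `start`.
#'
#' @seealso [readGenBank()], [extractGeneOrder()], [countCodons()]
#' @export
setClass("MitoGenome",
  representation(
    id = "character",
    length = "integer",
    circular = "logical",
    sequence = "character",
    features = "data.frame"
  )
)

setValidity("MitoGenome", function(object) {
  msg <- character(0)
  L <- object@length
  if (length(L) != 1L || is.na(L) || L <= 0L)
    msg <- c(msg, "length must be a single positive integer")
  if (!is.na(object@sequence) && nchar(object@sequence) != L)
    msg <- c(msg, "sequence length does not equal genome length")
  f <- object@features
  need <- c("name", "kind", "strand", "start", "end", "pseudo", "copy",
            "anticodon")
  if (!all(need %in% names(f))) {
    msg <- c(msg, paste("features must have columns:",
                        paste(need, collapse = ", ")))
  } else if (nrow(f)) {
    if (any(!f$kind %in% .GENE_KINDS))
      msg <- c(msg, "unknown feature kind")
    if (any(!f$strand %in% c("+", "-")))
      msg <- c(msg, "strand must be '+' or '-'")
    if (any(f$start < 0L | f$start >= L))
      msg <- c(msg, "feature start outside [0, length)")
    len <- (f$end - f$start) %% L
    if (any(len <= 0L))
      msg <- c(msg, "zero-length feature (end == start mod length)")
    if (is.unsorted(f$start))
      msg <- c(msg, "features must be sorted by start")
    for (nm in unique(f$name)) {
      ci <- f$copy[f$name == nm]
      if (!identical(as.integer(ci), seq_along(ci)))
        msg <- c(msg, sprintf("copy indices for '%s' not consecutive from 1",
                              nm))
    }
  }
  if (length(msg)) msg else TRUE
})

#' GeneOrder: a circular, strand- and pseudogene-aware gene arrangement
#'
#' Abstracts a genome's organization as a circular sequence of tokens
#' `(name, strand, pseudo, copy)`. Two orders are equal iff one is a
#' rotation of the other with identical token attributes (see
#' [orderEqual()]).
#'
#' @slot tokens data.frame with columns `name`, `strand`, `pseudo`,
#'   `copy`; row order is circle scan order linearized at the display
#'   origin (by convention, the token following the control region's
#'   3' end).
#' @export
setClass("GeneOrder", representation(tokens = "data.frame"))

setValidity("GeneOrder", function(object) {
  tk <- object@tokens
  need <- c("name", "strand", "pseudo", "copy")
  if (!all(need %in% names(tk)))
    return(paste("tokens must have columns:", paste(need, collapse = ", ")))
  if (nrow(tk) == 0L) return("zero-length gene order")
  if (any(!tk$strand %in% c("+", "-"))) return("strand must be '+' or '-'")
  TRUE
})

#' TDRLScenario: one tandem duplication-random loss event
#'
#' A contiguous interval `[from, to]` of an ancestral gene-order segment
#' is duplicated in tandem; each gene's two copies are then assigned
#' fates: exactly one copy `retained`, the other `pseudogenized` or
#' `deleted`. Applying the scenario ([applyTDRL()]) reproduces the
#' derived segment exactly.
#'
#' @slot genes gene names of the duplicated interval, in ancestral order.
#' @slot from,to 1-based interval bounds in the ancestral segment.
#' @slot fate1,fate2 per-gene fates of the first (left) and second
#'   (right) tandem copy; values in `retained`, `pseudogenized`,
#'   `deleted`.
#' @slot cost integer pair: (number of duplicated genes, number of
#'   non-retained copies); scenarios are ranked lexicographically.
#' @export
setClass("TDRLScenario",
  representation(
    genes = "character",
    from = "integer",
    to = "integer",
    fate1 = "character",
    fate2 = "character",
    cost = "integer"
  )
)

setValidity("TDRLScenario", function(object) {
  m <- length(object@genes)
  if (m == 0L) return("empty duplication interval")
  if (length(object@fate1) != m || length(object@fate2) != m)
    return("fate vectors must match interval length")
  ok <- c("retained", "pseudogenized", "deleted")
  if (any(!c(object@fate1, object@fate2) %in% ok))
    return("invalid fate value")
  if (any((object@fate1 == "retained") == (object@fate2 == "retained")))
    return("exactly one copy of each gene must be retained")
  if (object@to - object@from + 1L != m)
    return("interval bounds inconsistent with gene count")
  TRUE
})

#' CodonUsageTable: codon counts for one genome
#'
#' Codon counts of the mitochondrial protein-coding genes, per gene and
#' pooled. Stop codons are never counted; codons containing ambiguity
#' characters are skipped and tallied in `ambiguousSkipped`.
#'
#' @slot genomeId genome identifier.
#' @slot perGene named list: gene -> named integer vector of codon counts
#'   (DNA alphabet, e.g. `"ATG"`).
#' @slot pooled named integer vector summing `perGene`.
#' @slot totalCodons total pooled count.
#' @slot ambiguousSkipped number of codons skipped for ambiguity.
#' @slot internalStopGenes genes flagged for internal stop codons
#'   (pseudogene suspicion).
#' @export
setClass("CodonUsageTable",
  representation(
    genomeId = "character",
    perGene = "list",
    pooled = "numeric",
    totalCodons = "numeric",
    ambiguousSkipped = "numeric",
    internalStopGenes = "character"
  )
)

setValidity("CodonUsageTable", function(object) {
  if (any(object@pooled < 0)) return("negative codon count")
  agg <- Reduce(`+`, lapply(object@perGene, function(x) {
    v <- setNames(numeric(length(object@pooled)), names(object@pooled))
    v[names(x)] <- x
    v
  }), init = setNames(numeric(length(object@pooled)), names(object@pooled)))
  if (length(object@pooled) && any(abs(agg - object@pooled) > 1e-9))
    return("pooled counts do not equal the per-gene sum")
  if (abs(sum(object@pooled) - object@totalCodons) > 1e-9)
    return("totalCodons does not equal sum of pooled counts")
  if (any(names(object@pooled) %in% mitoStopCodons()))
    return("stop codons must not be counted")
  TRUE
})
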