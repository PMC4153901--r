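# Accessors and show methods.

#' @rdname MitoGenome-class
#' @export
setMethod("features", "MitoGenome", function(object) object@features)

#' @rdname MitoGenome-class
#' @export
setMethod("genomeId", "MitoGenome", function(object) object@id)

#' @rdname MitoGenome-class
#' @export
setMethod("genomeLength", "MitoGenome", function(object) object@length)

#' @rdname MitoGenome-class
#' @export
setMethod("genomeSequence", "MitoGenome", function(object) object@sequence)

setMethod("show", "MitoGenome", function(object) {
  f <- object@features
  cat(sprintf("MitoGenome '%s': %d bp, %s, %d features%s\n",
              object@id, object@length,
              if (object@circular) "circular" else "linear",
              nrow(f),
              if (is.na(object@sequence)) " (no sequence)" else ""))
  if (nrow(f)) {
    kinds <- table(f$kind)
    cat("  ", paste(sprintf("%s: %d", names(kinds), kinds),
                    collapse = ", "), "\n", sep = "")
    if (any(f$pseudo))
      cat("  pseudogenes: ",
          paste(f$name[f$pseudo], collapse = ", "), "\n", sep = "")
  }
})

#' @rdname GeneOrder-class
#' @export
setMethod("orderTokens", "GeneOrder", function(object) object@tokens)

#' @rdname GeneOrder-class
#' @param x a `GeneOrder` object.
#' @param ... ignored.
#' @export
setMethod("length", "GeneOrder", function(x) nrow(x@tokens))

setMethod("show", "GeneOrder", function(object) {
  cat(sprintf("GeneOrder with %d tokens:\n", nrow(object@tokens)))
  cat("  ", paste(orderTokenStrings(object), collapse = " "), "\n",
      sep = "")
})

setMethod("show", "TDRLScenario", function(object) {
  m <- length(object@genes)
  cat(sprintf(
    "TDRLScenario: tandem duplication of %d gene(s) [%d..%d], cost (%d, %d)\n",
    m, object@from, object@to, object@cost[1], object@cost[2]))
  fmt <- function(g, fate) switch(fate,
    retained = g, pseudogenized = paste0(g, "'"), deleted = ".")
  cat("  copy 1: ",
      paste(mapply(fmt, object@genes, object@fate1), collapse = " "),
      "\n", sep = "")
  cat("  copy 2: ",
      paste(mapply(fmt, object@genes, object@fate2), collapse = " "),
      "\n", sep = "")
})

setMethod("show", "CodonUsageTable", function(object) {
  cat(sprintf(
    "CodonUsageTable '%s': %d codons over %d gene(s)",
    object@genomeId, as.integer(object@totalCodons),
    length(object@perGene)))
  if (object@ambiguousSkipped > 0)
    cat(sprintf("; %d ambiguous codons skipped",
                as.integer(object@ambiguousSkipped)))
  if (length(object@internalStopGenes))
    cat("; internal stops in: ",
        paste(object@internalStopGenes, collapse = ", "), sep = "")
  cat("\n")
})
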