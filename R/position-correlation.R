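# tRNA gene position relative to the control region, and its
# correlation with usage of the decoded codons -- the test of adaptive
# gene positioning.

#' Physical distance of each tRNA gene from the control region
#'
#' The circle is linearized at the 3' end of the control region
#' (position 0) and walked in annotation (heavy-strand transcription)
#' direction. The distance of a tRNA is the offset of its 5' end: the
#' start coordinate for `+` strand genes, the annotation-end coordinate
#' for `-` strand genes. Distances are directed arcs modulo the genome
#' length, so they are never negative and are invariant under rotation
#' of the coordinate numbering; set `direction = "min"` for the
#' minimum-arc alternative. Pseudogene tRNAs are excluded. For genomes
#' with duplicated CRs or tRNAs the first copy in scan order is used:
#' the first CR from coordinate 0, and for each tRNA isotype the copy
#' closest downstream of the CR 3' end.
#'
#' @param genome a [MitoGenome-class] object with at least one CR
#'   feature and one functional tRNA.
#' @param direction `"downstream"` (default) or `"min"`.
#' @return named numeric vector: tRNA token -> distance in bp.
#' @export
trnaCrDistances <- function(genome, direction = c("downstream", "min")) {
  direction <- match.arg(direction)
  f <- genome@features
  L <- genome@length
  cr <- f[f$kind == "CR" & !f$pseudo, , drop = FALSE]
  if (!nrow(cr))
    stop("no control region annotated in genome '", genome@id,
         "'; cannot measure tRNA distances")
  crEnd <- cr$end[1L] # 3' end of the first CR in scan order
  tr <- f[f$kind == "tRNA" & !f$pseudo, , drop = FALSE]
  if (!nrow(tr))
    stop("no functional tRNA genes in genome '", genome@id, "'")
  fiveP <- ifelse(tr$strand == "+", tr$start, .modLen(tr$end - 1L, L))
  dist <- .modLen(fiveP - crEnd, L)
  if (direction == "min") dist <- pmin(dist, L - dist)
  # first copy per isotype: the copy closest downstream of the CR
  ord <- order(dist)
  tr <- tr[ord, , drop = FALSE]
  dist <- dist[ord]
  keep <- !duplicated(tr$name)
  setNames(dist[keep], tr$name[keep])
}

#' Assemble the (distance, usage) dataset across genomes
#'
#' One record per genome and functional tRNA isotype (first copies
#' only): the tRNA's distance from the CR ([trnaCrDistances()]), the
#' pooled usage of the codons it decodes ([usageByTrna()]), and the
#' hydropathy class of the decoded amino acid. Genomes that fail
#' (missing CR, missing sequence) are skipped with a message.
#'
#' @param genomes list of [MitoGenome-class] objects with sequences.
#' @param map tRNA-to-codon map, default [trnaCodonMap()].
#' @param usage `"count"` (default, raw codon counts) or `"frequency"`
#'   (counts divided by the genome's total).
#' @return data.frame with columns `species`, `trna`, `distance`,
#'   `usage`, `hydropathy`.
#' @export
assembleDataset <- function(genomes, map = trnaCodonMap(),
                            usage = c("count", "frequency")) {
  usage <- match.arg(usage)
  rows <- list()
  for (g in genomes) {
    rec <- tryCatch({
      d <- trnaCrDistances(g)
      u <- usageByTrna(countCodons(g), map)
      trna <- names(d)
      data.frame(species = g@id, trna = trna,
                 distance = unname(d),
                 usage = if (usage == "count") unname(u[trna])
                         else unname(u[trna]) / sum(u),
                 hydropathy = trnaHydropathy(trna),
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      message(sprintf("skipping genome '%s': %s", g@id,
                      conditionMessage(e)))
      NULL
    })
    if (!is.null(rec)) rows[[length(rows) + 1L]] <- rec
  }
  if (!length(rows))
    stop("no usable genomes: every genome was skipped")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlate tRNA distance from the CR with codon usage
#'
#' Pearson correlation on the raw (distance, usage) pairs and Spearman
#' rank correlation on average ranks (midranks for ties), both with
#' two-tailed p-values from the t approximation with n - 2 degrees of
#' freedom.
#'
#' @param records data.frame from [assembleDataset()] (needs columns
#'   `distance` and `usage`), n >= 3.
#' @return list with `pearson_r`, `pearson_p`, `spearman_rho`,
#'   `spearman_p`, `n`.
#' @export
correlateUsage <- function(records) {
  x <- records$distance
  y <- records$usage
  n <- length(x)
  if (n < 3L) stop("need at least 3 records for a correlation")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("undefined correlation: constant input vector")
  pe <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  sp <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = FALSE,
             alternative = "two.sided"))
  list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       n = n)
}

#' Correlation report over named genome sets
#'
#' For each named set of genomes (e.g. an AGO set and an RGO set),
#' reports the pooled correlation over all records, the per-species
#' correlations, and per-hydropathy-class pooled correlations.
#'
#' @param genomeSets named list; each element a list of
#'   [MitoGenome-class] objects.
#' @param map tRNA-to-codon map, default [trnaCodonMap()].
#' @return data.frame with columns `set`, `scope`, `pearson_r`,
#'   `pearson_p`, `spearman_rho`, `spearman_p`, `n`.
#' @export
correlationReport <- function(genomeSets, map = trnaCodonMap()) {
  if (is.null(names(genomeSets)) || any(!nzchar(names(genomeSets))))
    stop("genomeSets must be a named list")
  rows <- list()
  addRow <- function(set, scope, records) {
    res <- tryCatch(correlateUsage(records), error = function(e) NULL)
    if (is.null(res)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      set = set, scope = scope, pearson_r = res$pearson_r,
      pearson_p = res$pearson_p, spearman_rho = res$spearman_rho,
      spearman_p = res$spearman_p, n = res$n, stringsAsFactors = FALSE)
  }
  for (setName in names(genomeSets)) {
    if (!length(genomeSets[[setName]]))
      stop("empty genome set: ", setName)
    ds <- assembleDataset(genomeSets[[setName]], map)
    addRow(setName, "pooled", ds)
    for (sp in unique(ds$species))
      addRow(setName, sp, ds[ds$species == sp, , drop = FALSE])
    for (hy in unique(ds$hydropathy))
      addRow(setName, paste0("pooled_", hy),
             ds[ds$hydropathy == hy, , drop = FALSE])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
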