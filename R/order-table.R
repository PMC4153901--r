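# Plain-text gene-order table: one row per genome with id, length and
# the comma-separated token string. Lossless with respect to GeneOrder.

#' Write a gene-order table
#'
#' Tab-separated table with one row per genome: id, genome length, and
#' the gene-order token string (minus-strand genes prefixed with `-`,
#' pseudogenes suffixed with `'`, tokens comma-separated). The format
#' round-trips through [readGeneOrderTable()].
#'
#' @param genomes non-empty list of [MitoGenome-class] objects, or a
#'   named list of [GeneOrder-class] objects (length written as NA).
#' @param path output path.
#' @param spacerMin passed to [extractGeneOrder()] for MitoGenome input.
#' @return `path`, invisibly.
#' @export
writeGeneOrderTable <- function(genomes, path, spacerMin = 30L) {
  if (!length(genomes)) stop("empty genome list")
  rows <- lapply(seq_along(genomes), function(i) {
    g <- genomes[[i]]
    if (is(g, "MitoGenome")) {
      ord <- extractGeneOrder(g, spacerMin = spacerMin)
      data.frame(id = g@id, length = g@length,
                 order = paste(orderTokenStrings(ord), collapse = ","),
                 stringsAsFactors = FALSE)
    } else if (is(g, "GeneOrder")) {
      id <- names(genomes)[i]
      if (is.null(id) || !nzchar(id)) id <- sprintf("order_%d", i)
      data.frame(id = id, length = NA_integer_,
                 order = paste(orderTokenStrings(g), collapse = ","),
                 stringsAsFactors = FALSE)
    } else stop("expected MitoGenome or GeneOrder")
  })
  tab <- do.call(rbind, rows)
  ok <- tryCatch({
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write gene-order table: ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read a gene-order table
#'
#' Inverse of [writeGeneOrderTable()].
#'
#' @param path path to a gene-order TSV.
#' @return named list of [GeneOrder-class] objects; genome lengths are
#'   attached as the `"length"` attribute of each order.
#' @export
readGeneOrderTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "length", "order") %in% names(tab)))
    stop("not a gene-order table: ", path)
  orders <- lapply(seq_len(nrow(tab)), function(i) {
    ord <- newGeneOrder(strsplit(tab$order[i], ",", fixed = TRUE)[[1]])
    attr(ord, "length") <- tab$length[i]
    ord
  })
  names(orders) <- tab$id
  orders
}
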