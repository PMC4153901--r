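# Gene-order representation, reference arrangements, extraction from
# annotated genomes, AGO/RGO classification and adjacency distance.

# The vertebrate ancestral gene order (AGO), linearized at the token
# following the control region's 3' end. Minus-strand genes carry "-".
.VERT_AGO <- c(
  "trnF", "rrnS", "trnV", "rrnL", "trnL(UUR)", "nad1", "trnI", "-trnQ",
  "trnM", "nad2", "trnW", "-trnA", "-trnN", "OL", "-trnC", "-trnY",
  "cox1", "-trnS(UCN)", "trnD", "cox2", "trnK", "atp8", "atp6", "cox3",
  "trnG", "nad3", "trnR", "nad4L", "nad4", "trnH", "trnS(AGY)",
  "trnL(CUN)", "nad5", "-nad6", "-trnE", "cob", "trnT", "-trnP", "CR")

# The neobatrachian arrangement: identical to the AGO except that
# trnL(CUN), trnT, trnP and trnF are rearranged into the LTPF cluster
# immediately upstream of the CR.
.NEO_LTPF <- c(
  "rrnS", "trnV", "rrnL", "trnL(UUR)", "nad1", "trnI", "-trnQ", "trnM",
  "nad2", "trnW", "-trnA", "-trnN", "OL", "-trnC", "-trnY", "cox1",
  "-trnS(UCN)", "trnD", "cox2", "trnK", "atp8", "atp6", "cox3", "trnG",
  "nad3", "trnR", "nad4L", "nad4", "trnH", "trnS(AGY)", "nad5", "-nad6",
  "-trnE", "cob", "trnL(CUN)", "trnT", "-trnP", "trnF", "CR")

.parseTokenString <- function(x) {
  pseudo <- grepl("'$", x)
  x <- sub("'$", "", x)
  strand <- ifelse(grepl("^-", x), "-", "+")
  name <- sub("^-", "", x)
  data.frame(name = name, strand = strand, pseudo = pseudo,
             stringsAsFactors = FALSE)
}

#' Construct a GeneOrder
#'
#' @param tokens either a character vector of token strings (`"-trnQ"`
#'   for minus strand, trailing `"'"` for pseudogenes) or a data.frame
#'   with columns `name`, `strand`, `pseudo`.
#' @return a [GeneOrder-class] object. Copy indices are assigned per
#'   name in scan order.
#' @export
newGeneOrder <- function(tokens) {
  tk <- if (is.character(tokens)) .parseTokenString(tokens)
        else as.data.frame(tokens, stringsAsFactors = FALSE)
  if (is.null(tk$pseudo)) tk$pseudo <- FALSE
  if (is.null(tk$strand)) tk$strand <- "+"
  tk$copy <- as.integer(stats::ave(seq_len(nrow(tk)), tk$name,
                                   FUN = seq_along))
  rownames(tk) <- NULL
  new("GeneOrder", tokens = tk[, c("name", "strand", "pseudo", "copy")])
}

#' Token strings of a gene order
#'
#' Renders tokens in the package's string dialect: `-` prefix for the
#' minus strand, `'` suffix for pseudogenes.
#'
#' @param order a [GeneOrder-class] object.
#' @return character vector of token strings.
#' @export
orderTokenStrings <- function(order) {
  tk <- order@tokens
  paste0(ifelse(tk$strand == "-", "-", ""), tk$name,
         ifelse(tk$pseudo, "'", ""))
}

#' Reference mitochondrial gene orders
#'
#' `vertebrate_AGO` is the ancestral vertebrate arrangement of 37 genes
#' plus the control region (CR) and the light-strand replication origin
#' (OL); it contains the intact WANCY block (trnW, trnA, trnN, OL, trnC,
#' trnY). `neobatrachian_LTPF` differs only by the rearranged trnL(CUN),
#' trnT, trnP, trnF placement forming the LTPF cluster adjacent to the
#' CR, the arrangement diagnostic of neobatrachian frogs.
#'
#' @param name `"vertebrate_AGO"` or `"neobatrachian_LTPF"`.
#' @return a [GeneOrder-class] object.
#' @export
referenceOrder <- function(name = c("vertebrate_AGO",
                                    "neobatrachian_LTPF")) {
  if (!name[1] %in% c("vertebrate_AGO", "neobatrachian_LTPF"))
    stop("unknown reference order '", name[1],
         "'; available: vertebrate_AGO, neobatrachian_LTPF")
  name <- match.arg(name)
  newGeneOrder(switch(name, vertebrate_AGO = .VERT_AGO,
                      neobatrachian_LTPF = .NEO_LTPF))
}

.tokenSignature <- function(tk, ignore.copy = TRUE) {
  sig <- paste0(tk$strand, tk$name, ifelse(tk$pseudo, "'", ""))
  if (!ignore.copy) sig <- paste0(sig, "#", tk$copy)
  sig
}

# Smallest-rotation canonical form of a signature vector.
.canonicalRotation <- function(sig) {
  n <- length(sig)
  if (n <= 1L) return(sig)
  rots <- vapply(seq_len(n), function(i) {
    paste(sig[c(i:n, seq_len(i - 1L))], collapse = "\r")
  }, character(1))
  strsplit(min(rots), "\r", fixed = TRUE)[[1]]
}

#' Rotation-invariant equality of gene orders
#'
#' Two circular gene orders are equal iff one is a rotation of the
#' other with identical token attributes (name, strand, pseudogene
#' flag). Copy indices are ignored by default since they depend on the
#' arbitrary linearization point.
#'
#' @param a,b [GeneOrder-class] objects.
#' @param ignore.copy ignore copy indices (default `TRUE`).
#' @return logical.
#' @export
orderEqual <- function(a, b, ignore.copy = TRUE) {
  if (length(a) != length(b)) return(FALSE)
  sa <- .canonicalRotation(.tokenSignature(a@tokens, ignore.copy))
  sb <- .canonicalRotation(.tokenSignature(b@tokens, ignore.copy))
  identical(sa, sb)
}

#' Extract the gene order of an annotated genome
#'
#' Walks the feature circle in scan order, linearized at the token
#' following the control region's 3' end (or the first feature when no
#' CR is annotated). Annotated noncoding features and unannotated
#' inter-feature gaps shorter than `spacerMin` are omitted; longer ones
#' become explicit `spacer` tokens. Pseudogenes are retained with their
#' flag.
#'
#' @param genome a [MitoGenome-class] object.
#' @param spacerMin minimum spacer length (bp) to report, default 30.
#' @return a [GeneOrder-class] object.
#' @export
extractGeneOrder <- function(genome, spacerMin = 30L) {
  f <- genome@features
  if (!nrow(f)) stop("genome has no features: ", genome@id)
  L <- genome@length
  lens <- .featLength(f$start, f$end, L)
  keep <- !(f$kind == "noncoding" & lens < spacerMin)
  f <- f[keep, , drop = FALSE]
  lens <- lens[keep]
  n <- nrow(f)
  if (!n) stop("no reportable features in genome: ", genome@id)
  tokens <- data.frame(
    name = ifelse(f$kind == "noncoding", "spacer", f$name),
    strand = f$strand, pseudo = f$pseudo, stringsAsFactors = FALSE)
  # insert spacer tokens for unannotated gaps >= spacerMin
  absEnd <- f$start + lens
  gapAfter <- if (n > 1L) c(f$start[-1L], f$start[1L] + L) - absEnd
              else L - lens
  rows <- list()
  for (i in seq_len(n)) {
    rows[[length(rows) + 1L]] <- tokens[i, , drop = FALSE]
    if (gapAfter[i] >= spacerMin)
      rows[[length(rows) + 1L]] <- data.frame(
        name = "spacer", strand = "+", pseudo = FALSE,
        stringsAsFactors = FALSE)
  }
  tk <- do.call(rbind, rows)
  # linearize at the token following the first CR (scan order from 0)
  crAt <- which(tk$name == "CR")
  if (length(crAt)) {
    o <- crAt[1L]
    idx <- c(seq_len(nrow(tk))[-seq_len(o)], seq_len(o))
    tk <- tk[idx, , drop = FALSE]
  }
  newGeneOrder(tk)
}

.complement37 <- function() {
  c(trnaTokens(), "cox1", "cox2", "cox3", "cob", "atp6", "atp8",
    paste0("nad", 1:6), "nad4L", "rrnS", "rrnL")
}

.hasContiguousRun <- function(names, run) {
  n <- length(names)
  if (n < length(run)) return(FALSE)
  ext <- c(names, names[seq_len(length(run) - 1L)])
  for (i in seq_len(n)) {
    if (all(ext[i:(i + length(run) - 1L)] == run)) return(TRUE)
  }
  FALSE
}

#' Classify a gene order as ancestral (AGO) or rearranged (RGO)
#'
#' A gene order is labelled `AGO` iff its functional tokens are
#' rotation-equal to [referenceOrder]`("vertebrate_AGO")` (copy indices
#' ignored) and it carries no pseudogenes. Otherwise it is `RGO` and a
#' set of named diagnostic features is reported: presence of the LTPF
#' cluster, integrity of the WANCY block, translocation of trnH away
#' from its ancestral position after nad4, duplication of trnM,
#' per-gene duplications and losses relative to the 37-gene complement,
#' and the pseudogene list.
#'
#' @param order a [GeneOrder-class] object.
#' @return a list with elements `label` (`"AGO"`/`"RGO"`), `features`
#'   (character vector of diagnostic flags), `lost`, `duplicated`,
#'   `pseudogenes`.
#' @export
classifyOrder <- function(order) {
  tk <- order@tokens
  fun <- tk[!tk$pseudo & !tk$name %in% c("spacer", "noncoding"), ,
            drop = FALSE]
  funNames <- fun$name
  feats <- character(0)
  wancy <- .hasContiguousRun(
    funNames[funNames != "CR"],
    c("trnW", "trnA", "trnN", "OL", "trnC", "trnY"))
  if (wancy) feats <- c(feats, "WANCY_intact")
  if (.hasContiguousRun(funNames,
                        c("trnL(CUN)", "trnT", "trnP", "trnF")))
    feats <- c(feats, "LTPF_cluster")
  counts <- table(funNames[!funNames %in% c("CR", "OL")])
  pseudoNames <- .orEmpty(tk$name[tk$pseudo])
  # a pseudogenized gene leaves a relic: reported as pseudo, not lost
  lost <- setdiff(.complement37(), c(names(counts), pseudoNames))
  duplicated <- names(counts)[counts > 1L]
  pseudogenes <- .orEmpty(tk$name[tk$pseudo])
  if ("trnH" %in% funNames) {
    pos <- which(funNames == "trnH")[1L]
    prev <- funNames[if (pos == 1L) length(funNames) else pos - 1L]
    if (prev != "nad4") feats <- c(feats, "trnH_translocated")
  }
  if (sum(funNames == "trnM") > 1L) feats <- c(feats, "trnM_duplicated")
  if (length(pseudogenes))
    feats <- c(feats, paste0(unique(pseudogenes), "_pseudo"))
  if (length(lost)) feats <- c(feats, "gene_loss")
  if (length(duplicated)) feats <- c(feats, "gene_duplication")
  fo <- newGeneOrder(fun[, c("name", "strand", "pseudo")])
  isAGO <- length(pseudogenes) == 0L && length(lost) == 0L &&
    length(duplicated) == 0L &&
    orderEqual(fo, referenceOrder("vertebrate_AGO"), ignore.copy = TRUE)
  list(label = if (isAGO) "AGO" else "RGO",
       features = if (isAGO) "WANCY_intact" else unique(feats),
       lost = lost, duplicated = duplicated, pseudogenes = pseudogenes)
}

.adjacencyBag <- function(order) {
  tk <- order@tokens
  tk <- tk[!tk$pseudo, , drop = FALSE]
  sig <- paste0(tk$strand, tk$name)
  n <- length(sig)
  if (n == 0L) return(character(0))
  paste(sig, sig[c(seq_len(n)[-1L], 1L)], sep = "|")
}

.bagDiffCount <- function(a, b) {
  ta <- table(a)
  tb <- table(b)
  tot <- 0L
  for (k in names(ta)) {
    extra <- ta[[k]] - if (k %in% names(tb)) tb[[k]] else 0L
    if (extra > 0L) tot <- tot + extra
  }
  tot
}

#' Shared-adjacency distance between two gene orders
#'
#' Counts adjacent gene pairs (on the circle, strand-aware, pseudogenes
#' excluded) present in one order but not the other; the symmetric form
#' reported is the maximum of both directions. Identical orders and
#' rotations of the same order have distance 0; an inverted gene breaks
#' its adjacencies.
#'
#' @param a,b [GeneOrder-class] objects over comparable token alphabets.
#' @return non-negative integer.
#' @export
adjacencyDistance <- function(a, b) {
  ba <- .adjacencyBag(a)
  bb <- .adjacencyBag(b)
  max(.bagDiffCount(ba, bb), .bagDiffCount(bb, ba))
}

.LETTER_TO_TRNA <- c(
  F = "trnF", V = "trnV", I = "trnI", Q = "trnQ", M = "trnM", W = "trnW",
  A = "trnA", N = "trnN", C = "trnC", Y = "trnY", D = "trnD", K = "trnK",
  G = "trnG", R = "trnR", H = "trnH", E = "trnE", T = "trnT", P = "trnP",
  S = "trnS(AGY)", L = "trnL(CUN)")

#' Parse a compact gene-order string
#'
#' Parses the single-letter dialect used for rearrangement hotspots
#' (e.g. `"WA'N'OLANOL'CY"`): one-letter tRNA names, `OL`/`O_L_` for the
#' light-strand origin, a trailing `'` marking pseudogenes, and
#' lower-case multi-letter gene names (e.g. `nad3`) separated by `-`.
#' `S` and `L` denote trnS(AGY) and trnL(CUN).
#'
#' @param x order string.
#' @return character vector of segment tokens (pseudogenes suffixed
#'   with `'`), suitable for [inferTDRL()].
#' @export
parseOrderString <- function(x) {
  s <- gsub("[ –]", "", x) # spaces and en-dashes
  out <- character(0)
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    if (substr(s, i, i) == "-") { i <- i + 1L; next }
    if (toupper(substr(s, i, i + 3L)) == "O_L_") {
      tok <- "OL"; i <- i + 4L
    } else if (toupper(substr(s, i, i + 1L)) == "OL") {
      tok <- "OL"; i <- i + 2L
    } else if (grepl("^[a-z]", substr(s, i, i))) {
      m <- regmatches(substr(s, i, n),
                      regexpr("^[a-z]+[0-9]*[A-Za-z]?", substr(s, i, n)))
      # lower-case gene name like nad3, cox1, nad4L
      tok <- m
      i <- i + nchar(m)
    } else {
      ch <- substr(s, i, i)
      if (!ch %in% names(.LETTER_TO_TRNA))
        stop("unrecognized order-string letter: ", ch)
      tok <- unname(.LETTER_TO_TRNA[ch])
      i <- i + 1L
    }
    if (i <= n && substr(s, i, i) == "'") {
      tok <- paste0(tok, "'")
      i <- i + 1L
    }
    out <- c(out, tok)
  }
  out
}
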