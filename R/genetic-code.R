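# Vertebrate mitochondrial genetic code (NCBI transl_table 2) and the
# codon-family structure used throughout: synonymous families with Leu
# split into CUN/UUR and Ser into AGY/UCN, matching the two distinct
# tRNAs of each. The 22 families partition the 60 sense codons and are
# in one-to-one correspondence with the 22 tRNA isotypes.

.pkgCache <- new.env(parent = emptyenv())

#' Vertebrate mitochondrial genetic code
#'
#' Named character vector mapping the 64 DNA codons to one-letter amino
#' acids under NCBI translation table 2 (`AGA`/`AGG` = stop, `ATA` = Met,
#' `TGA` = Trp).
#'
#' @return named character vector of length 64.
#' @export
mitoGeneticCode <- function() {
  if (is.null(.pkgCache$code))
    .pkgCache$code <- Biostrings::getGeneticCode("2")
  .pkgCache$code
}

#' Stop codons of the vertebrate mitochondrial code
#'
#' @return character vector (`TAA`, `TAG`, `AGA`, `AGG`).
#' @export
mitoStopCodons <- function() {
  code <- mitoGeneticCode()
  names(code)[code == "*"]
}

#' Sense codons of the vertebrate mitochondrial code
#'
#' @return character vector of the 60 non-stop DNA codons.
#' @export
mitoSenseCodons <- function() {
  code <- mitoGeneticCode()
  names(code)[code != "*"]
}

# Amino acid (one-letter) -> tRNA token, with Leu/Ser handled separately.
.AA_TO_TRNA <- c(
  F = "trnF", I = "trnI", M = "trnM", V = "trnV", P = "trnP", T = "trnT",
  A = "trnA", Y = "trnY", H = "trnH", Q = "trnQ", N = "trnN", K = "trnK",
  D = "trnD", E = "trnE", C = "trnC", W = "trnW", R = "trnR", G = "trnG"
)

#' Map from tRNA isotypes to the codons they decode
#'
#' Returns the 22-entry map from tRNA token to the set of sense codons it
#' decodes under the vertebrate mitochondrial code. `trnL(CUN)` and
#' `trnL(UUR)` split the leucine codons, `trnS(AGY)` and `trnS(UCN)` the
#' serine codons; `trnM` decodes `ATA`/`ATG` and `trnW` decodes
#' `TGA`/`TGG`. The 22 codon sets partition the 60 sense codons.
#'
#' @return named list: tRNA token -> character vector of DNA codons.
#' @export
trnaCodonMap <- function() {
  if (!is.null(.pkgCache$trnaMap)) return(.pkgCache$trnaMap)
  code <- mitoGeneticCode()
  sense <- mitoSenseCodons()
  fam <- character(length(sense))
  names(fam) <- sense
  for (cdn in sense) {
    aa <- code[[cdn]]
    fam[cdn] <- switch(aa,
      L = if (substr(cdn, 1, 1) == "C") "trnL(CUN)" else "trnL(UUR)",
      S = if (substr(cdn, 1, 1) == "A") "trnS(AGY)" else "trnS(UCN)",
      .AA_TO_TRNA[[aa]]
    )
  }
  .pkgCache$trnaMap <- split(names(fam), fam)
  .pkgCache$trnaMap
}

# Codon -> tRNA token (equivalently, synonymous family id).
.codonFamily <- function() {
  if (is.null(.pkgCache$codonFam)) {
    m <- trnaCodonMap()
    .pkgCache$codonFam <- setNames(
      rep(names(m), lengths(m)), unlist(m, use.names = FALSE))
  }
  .pkgCache$codonFam
}

#' All 22 mitochondrial tRNA isotype tokens
#'
#' @return character vector in ancestral-genome scan order.
#' @export
trnaTokens <- function() {
  c("trnF", "trnV", "trnL(UUR)", "trnI", "trnQ", "trnM", "trnW", "trnA",
    "trnN", "trnC", "trnY", "trnS(UCN)", "trnD", "trnK", "trnG", "trnR",
    "trnH", "trnS(AGY)", "trnL(CUN)", "trnE", "trnT", "trnP")
}

# Canonical anticodons (DNA alphabet) for feature annotation.
.TRNA_ANTICODON <- c(
  "trnF" = "GAA", "trnV" = "TAC", "trnL(UUR)" = "TAA", "trnI" = "GAT",
  "trnQ" = "TTG", "trnM" = "CAT", "trnW" = "TCA", "trnA" = "TGC",
  "trnN" = "GTT", "trnC" = "GCA", "trnY" = "GTA", "trnS(UCN)" = "TGA",
  "trnD" = "GTC", "trnK" = "TTT", "trnG" = "TCC", "trnR" = "TCG",
  "trnH" = "GTG", "trnS(AGY)" = "GCT", "trnL(CUN)" = "TAG",
  "trnE" = "TTC", "trnT" = "TGT", "trnP" = "TGG"
)

#' Hydropathy class of the amino acid decoded by a tRNA
#'
#' Classification used only for grouping and plotting: hydrophobic =
#' Gly, Ala, Val, Leu, Ile, Pro, Phe, Met, Trp, Cys; all other residues
#' hydrophilic.
#'
#' @param trna character vector of tRNA tokens.
#' @return character vector, `"hydrophobic"` or `"hydrophilic"`.
#' @export
trnaHydropathy <- function(trna) {
  hydrophobic <- c("trnG", "trnA", "trnV", "trnL(UUR)", "trnL(CUN)",
                   "trnI", "trnP", "trnF", "trnM", "trnW", "trnC")
  ifelse(trna %in% hydrophobic, "hydrophobic", "hydrophilic")
}
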