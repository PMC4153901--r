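# GenBank flat-file reader/writer for annotated mitogenomes, plus gene
# nomenclature normalization. Internally coordinates are 0-based
# half-open on the circle; GenBank's 1-based inclusive locations are
# converted on read and write. Origin-wrapping features use
# join(x..L,1..y) externally and start > end internally.

.AA3_TO_TRNA <- c(
  Phe = "trnF", Val = "trnV", Ile = "trnI", Gln = "trnQ", Met = "trnM",
  Trp = "trnW", Ala = "trnA", Asn = "trnN", Cys = "trnC", Tyr = "trnY",
  Asp = "trnD", Lys = "trnK", Gly = "trnG", Arg = "trnR", His = "trnH",
  Glu = "trnE", Thr = "trnT", Pro = "trnP"
)

.ANTICODON_TO_LS <- c(
  TAA = "trnL(UUR)", TAG = "trnL(CUN)", GCT = "trnS(AGY)",
  TGA = "trnS(UCN)", UAA = "trnL(UUR)", UAG = "trnL(CUN)",
  GCU = "trnS(AGY)", UGA = "trnS(UCN)"
)

.nameMap <- function() {
  if (is.null(.pkgCache$nameMap)) {
    path <- system.file("extdata", "gene_name_map.tsv",
                        package = "mitoRearr", mustWork = TRUE)
    tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    .pkgCache$nameMap <- tab
  }
  .pkgCache$nameMap
}

.normKey <- function(x) gsub("[ _]", "", toupper(x))

#' Normalize a gene name to its MitoZoa-style token
#'
#' Looks the name up in the package's versioned normalization table
#' (GenBank dialects such as `COI`, `MT-CO1`, `ND5`, `CYTB`, `D-loop`
#' map to `cox1`, `nad5`, `cob`, `CR`, ...). tRNA names of the form
#' `tRNA-Xxx` are resolved through the amino acid, with `Leu`/`Ser`
#' disambiguated by a `(UUR)`/`(CUN)`/`(AGY)`/`(UCN)` suffix or an
#' anticodon. Already-normalized tokens pass through unchanged.
#'
#' @param name raw gene/product name.
#' @param anticodon optional anticodon used to resolve Leu/Ser isotypes.
#' @return list with elements `token` (character or NA) and `kind`.
#' @export
normalizeGeneName <- function(name, anticodon = NA_character_) {
  known <- c(trnaTokens(), "cox1", "cox2", "cox3", "cob", "atp6", "atp8",
             paste0("nad", 1:6), "nad4L", "rrnS", "rrnL", "CR", "OL",
             "spacer")
  if (name %in% known) {
    kind <- if (name %in% trnaTokens()) "tRNA"
      else if (name %in% c("rrnS", "rrnL")) "rRNA"
      else if (name == "CR") "CR"
      else if (name == "OL") "OL"
      else if (name == "spacer") "noncoding"
      else "CDS"
    return(list(token = name, kind = kind))
  }
  key <- .normKey(name)
  tab <- .nameMap()
  hit <- match(key, .normKey(tab$alias))
  if (!is.na(hit))
    return(list(token = tab$token[hit], kind = tab$kind[hit]))
  # tRNA-Xxx forms, possibly with codon-family or anticodon parentheticals
  m <- regmatches(name, regexec("^TRN[A-Z]$|^tRNA[- ]?([A-Za-z]{3})", name))[[1]]
  if (length(m) == 2L && nzchar(m[2])) {
    aa <- paste0(toupper(substr(m[2], 1, 1)), tolower(substr(m[2], 2, 3)))
    if (aa %in% c("Leu", "Ser")) {
      fam <- regmatches(name, regexec("\\(([A-Za-z]{3})\\)", name))[[1]]
      famKey <- if (length(fam) == 2L) toupper(fam[2]) else NA_character_
      tok <- switch(aa, Leu = c(UUR = "trnL(UUR)", CUN = "trnL(CUN)",
                                TTR = "trnL(UUR)", CTN = "trnL(CUN)"),
                        Ser = c(AGY = "trnS(AGY)", UCN = "trnS(UCN)",
                                AGC = "trnS(AGY)", TCN = "trnS(UCN)"))
      if (!is.na(famKey) && famKey %in% names(tok))
        return(list(token = unname(tok[famKey]), kind = "tRNA"))
      if (!is.na(anticodon)) {
        ac <- toupper(anticodon)
        if (ac %in% names(.ANTICODON_TO_LS))
          return(list(token = unname(.ANTICODON_TO_LS[ac]), kind = "tRNA"))
      }
      warning(sprintf(
        "cannot resolve %s isotype for '%s'; defaulting to %s", aa, name,
        if (aa == "Leu") "trnL(UUR)" else "trnS(UCN)"))
      return(list(token = if (aa == "Leu") "trnL(UUR)" else "trnS(UCN)",
                  kind = "tRNA"))
    }
    if (aa %in% names(.AA3_TO_TRNA))
      return(list(token = unname(.AA3_TO_TRNA[aa]), kind = "tRNA"))
  }
  list(token = NA_character_, kind = "noncoding")
}

#' Construct a MitoGenome
#'
#' Sorts features by start, assigns consecutive copy indices per gene
#' name in scan order, and validates the object.
#'
#' @param id genome identifier.
#' @param length genome length (bp).
#' @param features data.frame with columns `name`, `kind`, `strand`,
#'   `start`, `end`, and optionally `pseudo` and `anticodon`.
#' @param sequence optional nucleotide string of length `length`.
#' @param circular logical; default `TRUE`.
#' @return a [MitoGenome-class] object.
#' @export
newMitoGenome <- function(id, length, features,
                          sequence = NA_character_, circular = TRUE) {
  f <- as.data.frame(features, stringsAsFactors = FALSE)
  if (is.null(f$pseudo)) f$pseudo <- FALSE
  if (is.null(f$anticodon)) f$anticodon <- NA_character_
  f$start <- as.integer(f$start)
  f$end <- as.integer(.modLen(f$end, length))
  f <- f[order(f$start), , drop = FALSE]
  f$copy <- stats::ave(seq_len(nrow(f)), f$name, FUN = seq_along)
  f <- f[, c("name", "kind", "strand", "start", "end", "pseudo", "copy",
             "anticodon")]
  rownames(f) <- NULL
  new("MitoGenome", id = as.character(id), length = as.integer(length),
      circular = isTRUE(circular),
      sequence = if (is.na(sequence)) NA_character_
                 else toupper(as.character(sequence)),
      features = f)
}

.parseLocation <- function(loc, L, circular, id) {
  raw <- gsub("[ <>]", "", loc)
  strand <- "+"
  x <- raw
  if (grepl("^complement\\(", x)) {
    strand <- "-"
    x <- sub("^complement\\((.*)\\)$", "\\1", x)
  }
  if (grepl("^(join|order)\\(", x)) {
    x <- sub("^(join|order)\\((.*)\\)$", "\\2", x)
    parts <- strsplit(x, ",")[[1]]
    rng <- do.call(rbind, lapply(parts, function(p) {
      ab <- as.integer(strsplit(p, "\\.\\.")[[1]])
      if (length(ab) == 1L) ab <- c(ab, ab)
      ab
    }))
    if (any(rng > L) || any(rng < 1L))
      stop(sprintf("coordinate outside [1, %d] in record '%s': %s",
                   L, id, loc))
    if (nrow(rng) == 2L && rng[1, 2] == L && rng[2, 1] == 1L && circular) {
      start <- rng[1, 1] - 1L
      end <- rng[2, 2]
    } else {
      start <- rng[1, 1] - 1L
      end <- rng[nrow(rng), 2]
    }
  } else {
    ab <- as.integer(strsplit(x, "\\.\\.")[[1]])
    if (length(ab) == 1L) ab <- c(ab, ab)
    if (any(is.na(ab)))
      stop(sprintf("unparseable location in record '%s': %s", id, loc))
    if (ab[2] > L || ab[1] < 1L)
      stop(sprintf("feature %s outside [1, %d] in record '%s'",
                   loc, L, id))
    start <- ab[1] - 1L
    end <- ab[2]
  }
  list(start = start, end = .modLen(end, L), strand = strand)
}

.parseQualifiers <- function(lines) {
  txt <- paste(trimws(lines), collapse = " ")
  quals <- list()
  for (m in regmatches(txt, gregexpr(
      '/[A-Za-z_]+(="[^"]*"|=[^" /][^ /]*)?', txt))[[1]]) {
    eq <- regexpr("=", m)
    if (eq < 0) {
      quals[[sub("^/", "", m)]] <- TRUE
    } else {
      key <- substr(m, 2L, eq - 1L)
      val <- gsub('^"|"$', "", substr(m, eq + 1L, nchar(m)))
      quals[[key]] <- val
    }
  }
  quals
}

.GB_KIND_BY_KEY <- c(CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                     "D-loop" = "CR", rep_origin = "OL")

#' Read annotated mitogenomes from a GenBank flat file
#'
#' Parses one or more records (LOCUS / FEATURES / ORIGIN) into
#' [MitoGenome-class] objects. Gene and product qualifiers are mapped to
#' normalized tokens via [normalizeGeneName()]; a `/pseudo` qualifier or
#' a trailing `'` in the name sets the pseudogene flag; tRNA anticodons
#' are parsed when present; circular topology is read from the LOCUS
#' line (defaulting to circular). Features with unrecognized names are
#' kept as `noncoding` with a warning, never dropped.
#'
#' @param path path to a GenBank flat file.
#' @return a list of [MitoGenome-class] objects (one per record).
#' @export
readGenBank <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  recEnds <- grep("^//", lines)
  if (!length(recEnds)) {
    if (!length(grep("^LOCUS", lines)))
      stop("not a GenBank flat file (no LOCUS line): ", path)
    recEnds <- length(lines)
  }
  recStarts <- c(1L, head(recEnds, -1L) + 1L)
  genomes <- list()
  for (r in seq_along(recEnds)) {
    rec <- lines[recStarts[r]:recEnds[r]]
    rec <- rec[!grepl("^//", rec)]
    if (!any(grepl("^LOCUS", rec))) next
    locus <- rec[grep("^LOCUS", rec)[1]]
    lt <- regmatches(locus, regexec("^LOCUS\\s+(\\S+).*?(\\d+)\\s+bp",
                                    locus))[[1]]
    if (length(lt) != 3L)
      stop("unparseable LOCUS line: ", locus)
    id <- lt[2]
    L <- as.integer(lt[3])
    circular <- !grepl("\\blinear\\b", locus, ignore.case = TRUE)
    featStart <- grep("^FEATURES", rec)
    originAt <- grep("^ORIGIN", rec)
    seqStr <- NA_character_
    if (length(originAt)) {
      seqLines <- rec[(originAt[1] + 1L):length(rec)]
      seqStr <- toupper(gsub("[^A-Za-z]", "", paste(seqLines, collapse = "")))
      if (!nzchar(seqStr)) seqStr <- NA_character_
      if (!is.na(seqStr) && nchar(seqStr) != L)
        stop(sprintf("ORIGIN sequence length (%d) != LOCUS length (%d) in '%s'",
                     nchar(seqStr), L, id))
    }
    feats <- list()
    if (length(featStart)) {
      lastLine <- if (length(originAt)) originAt[1] - 1L else length(rec)
      body <- rec[(featStart[1] + 1L):lastLine]
      keyAt <- grep("^ {2,5}\\S", body)
      for (k in seq_along(keyAt)) {
        blockEnd <- if (k < length(keyAt)) keyAt[k + 1L] - 1L
                    else length(body)
        block <- body[keyAt[k]:blockEnd]
        key <- sub("^\\s+", "", sub("^(\\s*\\S+).*$", "\\1", block[1]))
        locPart <- trimws(sub("^\\s*\\S+", "", block[1]))
        qualAt <- grep("^\\s{10,}/", block)
        if (length(qualAt)) {
          extra <- setdiff(2:max(2, qualAt[1] - 1L), 1L)
          if (length(extra) && qualAt[1] > 2L)
            locPart <- paste0(locPart,
                              paste(trimws(block[2:(qualAt[1] - 1L)]),
                                    collapse = ""))
          quals <- .parseQualifiers(block[qualAt[1]:length(block)])
        } else {
          if (length(block) > 1L)
            locPart <- paste0(locPart, paste(trimws(block[-1]), collapse = ""))
          quals <- list()
        }
        if (key == "source") next
        pos <- .parseLocation(locPart, L, circular, id)
        if (!circular && pos$end != 0 && pos$end <= pos$start)
          stop(sprintf("wrapping feature on linear record '%s'", id))
        anticodon <- NA_character_
        if (!is.null(quals$anticodon)) {
          ac <- quals$anticodon
          m <- regmatches(ac, regexec("seq:([A-Za-z]{3})", ac))[[1]]
          anticodon <- toupper(if (length(m) == 2L) m[2] else gsub("[^A-Za-z]", "", ac))
          anticodon <- chartr("U", "T", anticodon)
          if (nchar(anticodon) != 3L) anticodon <- NA_character_
        }
        rawName <- quals$gene %||% quals$product %||% quals$note %||% ""
        pseudo <- isTRUE(quals$pseudo) || isTRUE(quals$pseudogene) ||
          is.character(quals$pseudogene) || grepl("'$", rawName)
        rawName <- sub("'$", "", rawName)
        kindFromKey <- .GB_KIND_BY_KEY[key]
        norm <- normalizeGeneName(rawName, anticodon)
        if (!is.na(norm$token)) {
          name <- norm$token
          kind <- if (!is.na(kindFromKey)) unname(kindFromKey) else norm$kind
        } else if (!is.na(kindFromKey) && kindFromKey %in% c("CR", "OL")) {
          name <- unname(kindFromKey)
          kind <- name
        } else if (nzchar(rawName)) {
          warning(sprintf("unknown gene name '%s' in '%s'; kept as noncoding",
                          rawName, id))
          name <- rawName
          kind <- "noncoding"
        } else {
          name <- "noncoding"
          kind <- "noncoding"
        }
        feats[[length(feats) + 1L]] <- data.frame(
          name = name, kind = kind, strand = pos$strand,
          start = pos$start, end = pos$end, pseudo = pseudo,
          anticodon = anticodon, stringsAsFactors = FALSE)
      }
    }
    featDf <- if (length(feats)) do.call(rbind, feats) else
      data.frame(name = character(0), kind = character(0),
                 strand = character(0), start = integer(0),
                 end = integer(0), pseudo = logical(0),
                 anticodon = character(0), stringsAsFactors = FALSE)
    genomes[[length(genomes) + 1L]] <-
      newMitoGenome(id, L, featDf, seqStr, circular)
  }
  if (!length(genomes)) stop("no GenBank records found in ", path)
  genomes
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.GB_KEY_BY_KIND <- c(CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                     CR = "D-loop", OL = "rep_origin",
                     noncoding = "misc_feature")

.formatLocation <- function(start, end, strand, L) {
  if (end == 0L) end <- L # feature running up to the numbering origin
  loc <- if (end > start) {
    sprintf("%d..%d", start + 1L, end)
  } else {
    sprintf("join(%d..%d,1..%d)", start + 1L, L, end)
  }
  if (strand == "-") loc <- sprintf("complement(%s)", loc)
  loc
}

#' Write a MitoGenome as a GenBank flat file
#'
#' Emits LOCUS, FEATURES and (when a sequence is present) ORIGIN
#' sections. Output is deterministic: no dates or run metadata are
#' written, so identical genomes yield byte-identical files.
#'
#' @param genome a [MitoGenome-class] object.
#' @param path output file path.
#' @param append append to the file (for multi-record files).
#' @return `path`, invisibly.
#' @export
writeGenBank <- function(genome, path, append = FALSE) {
  stopifnot(is(genome, "MitoGenome"))
  L <- genome@length
  out <- character(0)
  out <- c(out, sprintf("LOCUS       %-16s %d bp    DNA     %s     UNA",
                        genome@id, L,
                        if (genome@circular) "circular" else "linear"))
  out <- c(out, sprintf("DEFINITION  %s mitochondrial genome.", genome@id))
  out <- c(out, "FEATURES             Location/Qualifiers")
  out <- c(out, sprintf("     %-16s%s", "source", sprintf("1..%d", L)))
  out <- c(out, sprintf('                     /organelle="mitochondrion"'))
  f <- genome@features
  for (i in seq_len(nrow(f))) {
    key <- .GB_KEY_BY_KIND[[f$kind[i]]]
    loc <- .formatLocation(f$start[i], f$end[i], f$strand[i], L)
    out <- c(out, sprintf("     %-16s%s", key, loc))
    out <- c(out, sprintf('                     /gene="%s"', f$name[i]))
    if (f$kind[i] == "tRNA" && !is.na(f$anticodon[i]))
      out <- c(out, sprintf('                     /anticodon="%s"',
                            f$anticodon[i]))
    if (f$pseudo[i])
      out <- c(out, "                     /pseudo")
  }
  if (!is.na(genome@sequence)) {
    out <- c(out, "ORIGIN")
    s <- tolower(genome@sequence)
    starts <- seq(1L, nchar(s), by = 60L)
    for (st in starts) {
      chunk <- substr(s, st, min(st + 59L, nchar(s)))
      tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
      out <- c(out, sprintf("%9d %s", st, paste(tens, collapse = " ")))
    }
  }
  out <- c(out, "//")
  con <- file(path, open = if (append) "a" else "w")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Export a genome sequence as FASTA
#'
#' @param genome a [MitoGenome-class] object with a sequence.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGenomeFasta <- function(genome, path) {
  stopifnot(is(genome, "MitoGenome"))
  if (is.na(genome@sequence)) stop("genome has no sequence: ", genome@id)
  x <- Biostrings::DNAStringSet(genome@sequence)
  names(x) <- genome@id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
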