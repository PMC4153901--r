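# End-to-end pipeline orchestration: simulate or load genomes, then run
# the gene-order, codon-usage, correlation, TDRL and divergence stages
# into a reproducible output directory. All randomness flows from the
# single config seed via per-stage substreams.

.defaultStages <- c("orders", "codon_usage", "correlate", "tdrl", "dnds")

#' Run the analysis pipeline
#'
#' The configuration is a named list (or the path of a YAML file with
#' the same structure):
#' \describe{
#'   \item{seed}{integer master seed (default 1).}
#'   \item{outDir}{output directory (created if missing).}
#'   \item{simulate}{list of [simSpec()] arguments; mutually exclusive
#'     with `input`.}
#'   \item{input}{character vector of GenBank file paths.}
#'   \item{sets}{named list: set name -> genome ids, used for the
#'     correlation report (default: one set `all`).}
#'   \item{stages}{subset of `orders`, `codon_usage`, `correlate`,
#'     `tdrl`, `dnds` (default all).}
#'   \item{divergence}{list with `targetDS`, `targetDN`: each genome is
#'     paired with an evolved congeneric partner at these targets.}
#'   \item{tdrl}{list with `cases`: each a list with `ancestral` and
#'     `derived` compact order strings (see [parseOrderString()]).}
#'   \item{spacerMin, overlapOnce, distanceDirection}{stage switches
#'     forwarded to [extractGeneOrder()], [countCodons()] and
#'     [trnaCrDistances()].}
#' }
#'
#' Outputs written to `outDir`: `orders.tsv`, `codon_usage.tsv`,
#' `rscu.tsv`, `correlations.tsv`, `dnds.tsv`, `tdrl.json`, `run.log`,
#' and a verbatim `config.yaml` echo. Outputs are deterministic given
#' the config: a rerun with the same config and seed reproduces them
#' byte for byte.
#'
#' @param config named list or YAML file path.
#' @return the output directory, invisibly.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (is.null(config$outDir)) stop("config$outDir is required")
  seed <- as.integer(config$seed %||% 1L)
  stages <- config$stages %||% .defaultStages
  outDir <- config$outDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logLines <- c(sprintf("mitoRearr %s",
                        as.character(utils::packageVersion("mitoRearr"))),
                sprintf("R %s", as.character(getRversion())),
                sprintf("seed %d", seed))
  logIt <- function(...) logLines <<- c(logLines, sprintf(...))
  yaml::write_yaml(config, file.path(outDir, "config.yaml"))

  # --- inputs -------------------------------------------------------
  if (!is.null(config$simulate)) {
    args <- config$simulate
    args$seed <- args$seed %||% seed
    spec <- do.call(simSpec, args)
    sim <- generateCorrelatedSet(spec)
    genomes <- sim$genomes
    logIt("simulated %d genome(s)", length(genomes))
  } else if (!is.null(config$input)) {
    genomes <- unlist(lapply(config$input, readGenBank),
                      recursive = FALSE)
    logIt("read %d genome(s) from %d file(s)", length(genomes),
          length(config$input))
  } else stop("config must provide either 'simulate' or 'input'")
  if (!length(genomes)) stop("no input genomes")
  names(genomes) <- vapply(genomes, genomeId, character(1))
  spacerMin <- config$spacerMin %||% 30L

  # --- orders -------------------------------------------------------
  if ("orders" %in% stages) {
    rows <- lapply(genomes, function(g) {
      cls <- classifyOrder(extractGeneOrder(g, spacerMin = spacerMin))
      data.frame(id = g@id, length = g@length, label = cls$label,
                 features = paste(cls$features, collapse = ";"),
                 lost = paste(cls$lost, collapse = ";"),
                 duplicated = paste(cls$duplicated, collapse = ";"),
                 stringsAsFactors = FALSE)
    })
    write.table(do.call(rbind, rows), file.path(outDir, "orders.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeGeneOrderTable(genomes, file.path(outDir, "gene_orders.tsv"),
                        spacerMin = spacerMin)
    logIt("orders: %d genomes classified", length(genomes))
  }

  # --- codon usage & RSCU -------------------------------------------
  tables <- NULL
  if (any(c("codon_usage", "correlate") %in% stages)) {
    tables <- lapply(genomes, function(g) {
      tryCatch(countCodons(g, overlapOnce = isTRUE(config$overlapOnce)),
               error = function(e) {
                 logIt("skip codon usage for %s: %s", g@id,
                       conditionMessage(e))
                 NULL
               })
    })
    tables <- Filter(Negate(is.null), tables)
  }
  if ("codon_usage" %in% stages) {
    if (!length(tables)) stop("codon_usage stage: no usable genomes")
    usageRows <- lapply(tables, function(tb) {
      r <- rscu(tb)
      cbind(id = tb@genomeId, r, stringsAsFactors = FALSE)
    })
    all <- do.call(rbind, usageRows)
    write.table(all[, c("id", "codon", "aa", "count")],
                file.path(outDir, "codon_usage.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(all, file.path(outDir, "rscu.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    logIt("codon usage: %d genomes", length(tables))
  }

  # --- correlations -------------------------------------------------
  if ("correlate" %in% stages) {
    sets <- config$sets %||% list(all = names(genomes))
    genomeSets <- lapply(sets, function(ids) genomes[
      intersect(as.character(ids), names(genomes))])
    rep <- correlationReport(genomeSets)
    write.table(rep, file.path(outDir, "correlations.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    logIt("correlations: %d rows over %d set(s)", nrow(rep),
          length(genomeSets))
  }

  # --- TDRL ---------------------------------------------------------
  if ("tdrl" %in% stages && !is.null(config$tdrl$cases)) {
    out <- lapply(config$tdrl$cases, function(cs) {
      anc <- parseOrderString(cs$ancestral)
      der <- parseOrderString(cs$derived)
      scs <- inferTDRL(anc, der)
      list(ancestral = anc, derived = der,
           scenarios = lapply(scs, function(sc) list(
             interval = c(sc@from, sc@to), genes = sc@genes,
             fate_copy1 = sc@fate1, fate_copy2 = sc@fate2,
             cost = sc@cost)))
    })
    jsonlite::write_json(out, file.path(outDir, "tdrl.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    logIt("tdrl: %d case(s)", length(out))
  }

  # --- divergence ---------------------------------------------------
  if ("dnds" %in% stages && !is.null(config$divergence)) {
    dv <- config$divergence
    rows <- lapply(seq_along(genomes), function(i) {
      g <- genomes[[i]]
      partner <- evolvePair(g, dv$targetDS %||% 0.1, dv$targetDN %||% 0.02,
                            seed = .subSeed(seed, 900000L + i))$genome
      genomePairDivergence(g, partner)
    })
    write.table(do.call(rbind, rows), file.path(outDir, "dnds.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    logIt("dnds: %d pair(s)", length(rows))
  }

  writeLines(logLines, file.path(outDir, "run.log"))
  invisible(outDir)
}
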