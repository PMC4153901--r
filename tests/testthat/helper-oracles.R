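# Independent brute-force oracles used to check the package's
# implementations. These deliberately use the most direct formulation
# of each definition, independent of the package's code paths.

# --- direct-formula Pearson and Spearman ----------------------------
corOracle <- function(x, y) {
  pearsonOf <- function(u, v) {
    du <- u - sum(u) / length(u)
    dv <- v - sum(v) / length(v)
    sum(du * dv) / sqrt(sum(du^2) * sum(dv^2))
  }
  c(r = pearsonOf(x, y), rho = pearsonOf(rank(x), rank(y)))
}

# --- NG86 by explicit pathway enumeration ---------------------------
ng86Oracle <- function(a, b) {
  code <- Biostrings::getGeneticCode("2")
  stops <- names(code)[code == "*"]
  toCodons <- function(s) substring(s, seq(1, nchar(s) - 2, 3),
                                    seq(3, nchar(s), 3))
  ca <- toCodons(a)
  cb <- toCodons(b)
  n <- length(ca)
  if (ca[n] %in% stops || cb[n] %in% stops) {
    ca <- ca[-n]
    cb <- cb[-n]
  }
  synSites <- function(cdn) {
    syn <- 0
    for (pos in 1:3) for (nt in setdiff(c("A", "C", "G", "T"),
                                        substr(cdn, pos, pos))) {
      alt <- cdn
      substr(alt, pos, pos) <- nt
      if (code[[alt]] != "*" && code[[alt]] == code[[cdn]])
        syn <- syn + 1
    }
    syn / 3
  }
  # enumerate every ordering of the differing positions explicitly
  pathDiffs <- function(x, y) {
    pos <- which(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
    if (!length(pos)) return(c(0, 0))
    perms <- function(v) {
      if (length(v) <= 1) return(list(v))
      out <- list()
      for (q in seq_along(v))
        for (rest in perms(v[-q]))
          out[[length(out) + 1]] <- c(v[q], rest)
      out
    }
    walk <- function(ord, allowStop) {
      cur <- x
      sd <- 0
      nd <- 0
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(y, p, p)
        if (!allowStop && code[[nxt]] == "*") return(NULL)
        if (code[[nxt]] != "*" && code[[nxt]] == code[[cur]])
          sd <- sd + 1
        else nd <- nd + 1
        cur <- nxt
      }
      c(sd, nd)
    }
    ok <- Filter(Negate(is.null),
                 lapply(perms(pos), walk, allowStop = FALSE))
    if (!length(ok)) ok <- lapply(perms(pos), walk, allowStop = TRUE)
    Reduce(`+`, ok) / length(ok)
  }
  S <- (sum(vapply(ca, synSites, 0)) + sum(vapply(cb, synSites, 0))) / 2
  N <- 3 * length(ca) - S
  d <- Reduce(`+`, Map(pathDiffs, ca, cb))
  list(S = S, N = N, Sd = d[1], Nd = d[2])
}

# random sense-codon sequence pair (no stops) for NG86 oracle tests
randomCodingPair <- function(nCodons, nDiff) {
  sense <- mitoSenseCodons()
  a <- sample(sense, nCodons, replace = TRUE)
  b <- a
  idx <- sample(nCodons, min(nDiff, nCodons))
  b[idx] <- sample(sense, length(idx), replace = TRUE)
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}

# --- exhaustive single-TDRL enumerator ------------------------------
# Enumerates every (interval, fate assignment), applies it, and groups
# scenarios by the derived segment they produce.
tdrlScenarioBank <- function(anc) {
  n <- length(anc)
  bank <- new.env(parent = emptyenv())
  for (i in 1:n) for (j in i:n) {
    m <- j - i + 1L
    block <- anc[i:j]
    grid <- expand.grid(rep(list(1:4), m))
    for (r in seq_len(nrow(grid))) {
      f <- as.integer(grid[r, ])
      fate1 <- c("retained", "retained", "deleted", "pseudogenized")[f]
      fate2 <- c("deleted", "pseudogenized", "retained", "retained")[f]
      sc <- newTDRLScenario(block, i, j, fate1, fate2)
      key <- paste(applyTDRL(anc, sc), collapse = " ")
      bank[[key]] <- c(bank[[key]], list(sc))
    }
  }
  bank
}

scenarioKey <- function(sc) {
  paste(sc@from, sc@to, paste(sc@fate1, collapse = ","),
        paste(sc@fate2, collapse = ","), sep = ";")
}

minimalScenarios <- function(scs) {
  costs <- t(vapply(scs, function(s) s@cost, integer(2)))
  best <- costs[, 1] == min(costs[, 1])
  best[best] <- costs[best, 2] == min(costs[best, 2])
  scs[best]
}

# Checks inferTDRL against the bank for every derived of one ancestor;
# returns the number of mismatching derived cases.
tdrlAgreementErrors <- function(anc) {
  bank <- tdrlScenarioBank(anc)
  bad <- 0L
  for (key in ls(bank)) {
    der <- strsplit(key, " ", fixed = TRUE)[[1]]
    mine <- inferTDRL(anc, der)
    if (identical(der, anc)) {
      if (length(mine)) bad <- bad + 1L
      next
    }
    oracle <- sort(unique(vapply(minimalScenarios(bank[[key]]),
                                 scenarioKey, "")))
    got <- sort(vapply(mine, scenarioKey, ""))
    if (!identical(oracle, got)) bad <- bad + 1L
  }
  bad
}

# --- Mann-Whitney U by ordered-pair counting ------------------------
uOracle <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}
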