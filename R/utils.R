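# Circular-coordinate helpers. All genome coordinates are 0-based
# half-open; arithmetic is modulo the genome length.

.modLen <- function(x, L) ((x %% L) + L) %% L

# Length of a feature [start, end) on a circle of length L; end == start
# is invalid (never a full-circle feature).
.featLength <- function(start, end, L) {
  len <- .modLen(end - start, L)
  ifelse(len == 0L, L, len) # guarded by validity; kept total for safety
}

# Extract the subsequence [start, end) from a circular sequence given as
# a single string; wraps the origin when end <= start.
.circSubstr <- function(seq, start, end, L) {
  if (end > start) {
    substr(seq, start + 1L, end)
  } else {
    paste0(substr(seq, start + 1L, L), substr(seq, 1L, end))
  }
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Split a DNA string into codons, dropping a trailing partial codon.
.codonSplit <- function(x) {
  n <- nchar(x) %/% 3L
  if (n == 0L) return(character(0))
  substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# Deterministic substream seed derived from a master seed; kept below
# 2^31 so it is always a valid R integer seed.
.subSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(index) * 7919) %%
               2147483647)
}

.isDNA <- function(codon) !grepl("[^ACGT]", codon)

.orEmpty <- function(x) if (length(x)) x else character(0)
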