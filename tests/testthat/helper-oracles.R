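# Independent oracles used to cross-check the package implementations.
# These deliberately use different algorithms (plain string scans, explicit
# enumeration) from the code under test.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# character-by-character window scan; N in the subject matches nothing
oracleScan <- function(seqStr, motif) {
  n <- nchar(seqStr); m <- nchar(motif)
  if (n < m) return(integer())
  sc <- strsplit(seqStr, "")[[1]]
  mc <- strsplit(motif, "")[[1]]
  hits <- integer()
  for (s in 0:(n - m)) {
    ok <- TRUE
    for (j in seq_len(m)) {
      if (!(sc[s + j] %in% IUPAC_SETS[[mc[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

# fast exact-string scan for plain ACGT motifs (overlap-aware)
oracleScanExact <- function(seqStr, motif) {
  n <- nchar(seqStr); m <- nchar(motif)
  if (n < m) return(integer())
  starts <- 1:(n - m + 1)
  which(substring(seqStr, starts, starts + m - 1) == motif) - 1L
}

# brute-force double digestion: independent single-pass re-implementation
# returning 0-based half-open fragments with end labels
oracleDigest <- function(seqStr, primary, secondary = NULL) {
  len <- nchar(seqStr)
  cutsOf <- function(e) {
    hits <- oracleScanExact(seqStr, recognitionSite(e))
    cuts <- hits + cutOffset(e)
    sort(unique(cuts[cuts > 0 & cuts < len]))
  }
  cp <- cutsOf(primary)
  lab <- rep(enzymeName(primary), length(cp))
  allCuts <- cp
  if (!is.null(secondary)) {
    cs <- cutsOf(secondary)
    for (k in seq_along(cs)) {
      if (cs[k] %in% allCuts) {
        lab[allCuts == cs[k]] <- "AMBIGUOUS"
      } else {
        allCuts <- c(allCuts, cs[k])
        lab <- c(lab, enzymeName(secondary))
      }
    }
  }
  o <- order(allCuts)
  allCuts <- allCuts[o]; lab <- lab[o]
  b <- c(0L, allCuts, len)
  bl <- c("SEQ_END", lab, "SEQ_END")
  data.frame(start = b[-length(b)], end = b[-1],
             leftEnd = bl[-length(bl)], rightEnd = bl[-1],
             stringsAsFactors = FALSE)
}

# Mendelian consistency by explicit gamete enumeration
oracleMendel <- function(off, sire, dam) {
  gam <- function(g) switch(g + 1L, 0L, c(0L, 1L), 1L)
  for (a in gam(sire)) for (b in gam(dam))
    if (a + b == off) return("consistent")
  "error"
}

# exact HWE p-value by direct enumeration of all genotype configurations
# compatible with the observed allele counts, normalised multinomially
oracleHwe <- function(a, b, c_) {
  n <- a + b + c_
  nA <- 2L * a + b           # allele-1 count
  hmax <- min(nA, 2L * n - nA)
  hets <- seq.int(hmax %% 2L, hmax, by = 2L)
  lp <- sapply(hets, function(h) {
    aa <- (nA - h) / 2
    cc <- n - aa - h
    lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(cc) +
      h * log(2) +
      lfactorial(nA) + lfactorial(2 * n - nA) - lfactorial(2 * n)
  })
  p <- exp(lp)
  p <- p / sum(p)
  pObs <- p[hets == b]
  sum(p[p <= pObs * (1 + 1e-7)])
}

# naive 3' trim: drop trailing bases while the last base is below threshold
oracleTrailingTrim <- function(quals, threshold) {
  n <- length(quals)
  while (n > 0 && quals[n] < threshold) n <- n - 1L
  n
}

randomDNA <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

makeReads <- function(seqs, quals = NULL) {
  s <- Biostrings::DNAStringSet(seqs)
  if (is.null(quals))
    quals <- vapply(nchar(seqs), function(w) strrep("I", w), character(1))
  Biostrings::QualityScaledDNAStringSet(s, Biostrings::PhredQuality(quals))
}
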