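#' Expected fold coverage of captured sites
#'
#' Reduced-representation sequencing concentrates all reads of a sample onto
#' the captured portion of the genome, so the expected fold coverage of
#' captured sites is
#' \deqn{\mathrm{fold} = \frac{R \times L}{f \times G}}
#' with \eqn{R} reads per sample, \eqn{L} the read length, \eqn{f} the
#' capture fraction and \eqn{G} the genome length in bp. Coverage is linear
#' in the number of reads, which is what makes multiplexing arithmetic
#' simple: halving reads per sample halves coverage.
#'
#' @param readsPerSample number of (post-demultiplexing) reads per sample.
#' @param readLength read length in bp.
#' @param captureFraction fraction of the genome captured, in (0, 1].
#' @param genomeBp genome length in bp.
#' @return expected fold coverage (dimensionless).
#' @examples
#' # a 12-plex HiSeq lane: ~15.3e6 125 bp reads on a 3.4%-capture library
#' expectedCoverage(15.3e6, 125, 0.034, 2870182909)
#' @seealso [readsNeeded()] for the inverse.
#' @export
expectedCoverage <- function(readsPerSample, readLength, captureFraction,
                             genomeBp) {
  .checkCoverageArgs(readLength, captureFraction, genomeBp)
  if (any(readsPerSample < 0)) stop("readsPerSample must be >= 0")
  readsPerSample * readLength / (captureFraction * genomeBp)
}

#' Reads needed for a target coverage
#'
#' Inverse of [expectedCoverage()]: the number of reads per sample required
#' to reach a target fold coverage of captured sites.
#'
#' @param targetFold desired fold coverage.
#' @inheritParams expectedCoverage
#' @return reads per sample.
#' @export
readsNeeded <- function(targetFold, readLength, captureFraction, genomeBp) {
  .checkCoverageArgs(readLength, captureFraction, genomeBp)
  if (any(targetFold < 0)) stop("targetFold must be >= 0")
  targetFold * captureFraction * genomeBp / readLength
}

.checkCoverageArgs <- function(readLength, captureFraction, genomeBp) {
  if (any(captureFraction <= 0))
    stop("captureFraction must be > 0: coverage is undefined for an ",
         "empty capture")
  if (any(captureFraction > 1)) stop("captureFraction must be <= 1")
  if (any(readLength <= 0)) stop("readLength must be > 0")
  if (any(genomeBp <= 0)) stop("genomeBp must be > 0")
  invisible(TRUE)
}

#' Rank candidate secondary enzymes for a double digest
#'
#' Applies the hard selection criteria used when choosing a ddGBS secondary
#' enzyme — a short unambiguous recognition site, buffer compatibility with
#' the primary digest, a standard incubation temperature, sticky (non-blunt)
#' ends, and no methylation sensitivity — then digests the supplied genome
#' with the primary enzyme paired with each surviving candidate and ranks
#' survivors by the capture fraction of PS fragments in the size window.
#'
#' Blunt cutters are excluded because adapters cannot be ligated selectively
#' to blunt ends (random shear ends are blunt too); methylation-sensitive
#' enzymes are excluded because they would restrict the digest to a
#' methylation-dependent subset of the genome.
#'
#' @param genome sequences acceptable to [digestGenome()].
#' @param primary the primary [RestrictionEnzyme-class].
#' @param candidates list of candidate [RestrictionEnzyme-class] objects.
#' @param window a [SizeWindow-class].
#' @param recognitionLength required recognition length (default 4 bp);
#'   \code{NA} disables the check.
#' @param requireUnambiguous exclude IUPAC-ambiguous recognition sequences.
#' @param requireBufferCompatible,excludeMethylationSensitive,stickyOnly
#'   logical criteria flags.
#' @param incubationTemp required incubation temperature in Celsius;
#'   \code{NA} disables the check.
#' @return data.frame with one row per candidate: \code{enzyme},
#'   \code{recognition}, \code{overhang}, \code{excluded}, \code{reason},
#'   \code{captureFraction} (NA for excluded candidates). Survivors first,
#'   in decreasing capture order.
#' @export
rankSecondaryEnzymes <- function(genome, primary, candidates, window,
                                 recognitionLength = 4L,
                                 requireUnambiguous = TRUE,
                                 requireBufferCompatible = TRUE,
                                 excludeMethylationSensitive = TRUE,
                                 stickyOnly = TRUE,
                                 incubationTemp = 37) {
  if (length(candidates) == 0L)
    return(data.frame(enzyme = character(), recognition = character(),
                      overhang = integer(), excluded = logical(),
                      reason = character(), captureFraction = numeric()))
  rows <- lapply(candidates, function(e) {
    stopifnot(is(e, "RestrictionEnzyme"))
    reasons <- character()
    if (!is.na(recognitionLength) &&
        nchar(e@recognition) != recognitionLength)
      reasons <- c(reasons,
                   sprintf("recognition length != %d bp", recognitionLength))
    if (requireUnambiguous &&
        grepl("[^ACGT]", e@recognition))
      reasons <- c(reasons, "ambiguous recognition sequence")
    if (requireBufferCompatible && !e@bufferCompatible)
      reasons <- c(reasons, "buffer-incompatible")
    if (!is.na(incubationTemp) && e@incubationTemp != incubationTemp)
      reasons <- c(reasons, sprintf("incubation != %g°C", incubationTemp))
    if (stickyOnly && e@overhangLen == 0L)
      reasons <- c(reasons, "blunt")
    if (excludeMethylationSensitive && e@methylationSensitive)
      reasons <- c(reasons, "methylation-sensitive")
    data.frame(enzyme = e@name, recognition = e@recognition,
               overhang = e@overhangLen,
               excluded = length(reasons) > 0L,
               reason = paste(reasons, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$captureFraction <- NA_real_
  seqs <- .asDNAStringSet(genome)
  for (i in which(!tab$excluded)) {
    fr <- digestGenome(seqs, primary, candidates[[i]])
    tab$captureFraction[i] <- captureFraction(captureSummary(fr, window))
  }
  surv <- tab[!tab$excluded, , drop = FALSE]
  surv <- surv[order(-surv$captureFraction, surv$enzyme), , drop = FALSE]
  out <- rbind(surv, tab[tab$excluded, , drop = FALSE])
  rownames(out) <- NULL
  out
}
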