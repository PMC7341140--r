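#' @importFrom GenomicRanges GRanges mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom BiocGenerics start end width
NULL

#' Construct a size-selection window
#'
#' @param minLibrary,maxLibrary inclusive bounds of the library-molecule
#'   window in bp (the interval programmed on the size selector).
#' @param adapterOffset bp added to each insert by adapters and primers;
#'   default 125.
#' @return a [SizeWindow-class].
#' @examples
#' w <- sizeWindow(250, 400)
#' insertWindow(w)  # 125 275
#' @export
sizeWindow <- function(minLibrary, maxLibrary, adapterOffset = 125) {
  new("SizeWindow", minLibrary = as.numeric(minLibrary),
      maxLibrary = as.numeric(maxLibrary),
      adapterOffset = as.numeric(adapterOffset))
}

#' @describeIn SizeWindow-class the corresponding insert-scale window
#'   (library bounds minus the adapter offset), as \code{c(min, max)}.
#' @export
setMethod("insertWindow", "SizeWindow", function(x) {
  c(x@minLibrary - x@adapterOffset, x@maxLibrary - x@adapterOffset)
})

#' @describeIn SizeWindow-class display.
#' @param object a [SizeWindow-class].
#' @export
setMethod("show", "SizeWindow", function(object) {
  iw <- insertWindow(object)
  cat(sprintf("SizeWindow: library %g-%g bp (insert %g-%g bp, adapters +%g)\n",
              object@minLibrary, object@maxLibrary, iw[1], iw[2],
              object@adapterOffset))
})

.SEQ_END <- "SEQ_END"
.AMBIGUOUS <- "AMBIGUOUS"

## end-class of a fragment given its two end labels and the enzyme names
.endClass <- function(left, right, primary, secondary) {
  cls <- character(length(left))
  amb <- left == .AMBIGUOUS | right == .AMBIGUOUS
  term <- !amb & (left == .SEQ_END | right == .SEQ_END)
  cls[amb] <- "AMBIGUOUS"
  cls[term] <- "END"
  inner <- !amb & !term
  nPrim <- (left == primary) + (right == primary)
  cls[inner & nPrim == 2L] <- "PP"
  cls[inner & nPrim == 1L] <- "PS"
  cls[inner & nPrim == 0L] <- "SS"
  cls
}

## digest one DNAString; returns data.frame of 0-based half-open fragments
.digestOne <- function(subject, primary, secondary) {
  len <- length(subject)
  cutsP <- cutPositions(scanRecognitionSites(subject, primary), primary,
                        seqLength = len)
  labels <- rep(primary@name, length(cutsP))
  cuts <- cutsP
  if (!is.null(secondary)) {
    cutsS <- cutPositions(scanRecognitionSites(subject, secondary), secondary,
                          seqLength = len)
    shared <- intersect(cuts, cutsS)
    labels <- c(labels, rep(secondary@name, length(cutsS)))
    cuts <- c(cuts, cutsS)
    if (length(shared))
      labels[cuts %in% shared] <- .AMBIGUOUS
    keep <- !duplicated(cuts)
    cuts <- cuts[keep]
    labels <- labels[keep]
  }
  o <- order(cuts)
  cuts <- cuts[o]
  labels <- labels[o]
  bounds <- c(0L, cuts, len)
  blabels <- c(.SEQ_END, labels, .SEQ_END)
  n <- length(bounds) - 1L
  data.frame(
    start = bounds[-length(bounds)],
    end = bounds[-1L],
    leftEnd = blabels[seq_len(n)],
    rightEnd = blabels[-1L],
    stringsAsFactors = FALSE)
}

#' In silico digestion of a genome
#'
#' Digests one or more DNA sequences with a primary enzyme, optionally
#' paired with a secondary enzyme (double digest). The returned fragments
#' tile each input sequence exactly: consecutive, non-overlapping, covering
#' every base including assembly gaps (which can never be cut but still
#' count toward the digested total). Each internal fragment boundary is
#' labelled with the enzyme that produced it; a coordinate cut identically
#' by both enzymes is labelled \code{AMBIGUOUS} (its ligatable overhang is
#' undeterminable) and sequence termini are labelled \code{SEQ_END}.
#'
#' Fragment end classes are derived from the two end labels: \code{PP}
#' (both primary), \code{PS} (one primary, one secondary — the only class
#' amplifiable by a standard ddGBS adapter/primer design), \code{SS} (both
#' secondary), \code{END} (touching a sequence terminus) and
#' \code{AMBIGUOUS}.
#'
#' @param x a \code{DNAStringSet}, \code{DNAString}, character vector of
#'   sequences, or path to a FASTA file (gzip transparent).
#' @param primary a [RestrictionEnzyme-class].
#' @param secondary a [RestrictionEnzyme-class] or \code{NULL} for a single
#'   digest.
#' @return a \code{GRanges} (1-based, widths = fragment lengths) with
#'   metadata columns \code{leftEnd}, \code{rightEnd}, \code{endClass}.
#' @examples
#' cat <- enzymeCatalog()
#' fr <- digestGenome("AAACTGCAGTTTTTTTTTTCATGAAAA", cat$PstI, cat$NlaIII)
#' mcols(fr)$endClass
#' @export
digestGenome <- function(x, primary, secondary = NULL) {
  stopifnot(is(primary, "RestrictionEnzyme"))
  if (!is.null(secondary)) {
    stopifnot(is(secondary, "RestrictionEnzyme"))
    if (identical(primary@name, secondary@name))
      stop("primary and secondary enzymes must be distinct")
  }
  seqs <- .asDNAStringSet(x)
  frags <- lapply(seq_along(seqs), function(i)
    cbind(seqId = names(seqs)[i], .digestOne(seqs[[i]], primary, secondary),
          stringsAsFactors = FALSE))
  frags <- do.call(rbind, frags)
  # tiling conservation, asserted on every call
  tot <- tapply(frags$end - frags$start, frags$seqId, sum)
  stopifnot(all(tot[names(seqs)] == lengths(seqs)))
  gr <- GRanges(frags$seqId,
                IRanges(start = frags$start + 1L, end = frags$end))
  mcols(gr)$leftEnd <- frags$leftEnd
  mcols(gr)$rightEnd <- frags$rightEnd
  mcols(gr)$endClass <- .endClass(frags$leftEnd, frags$rightEnd,
                                  primary@name,
                                  if (is.null(secondary)) "" else
                                    secondary@name)
  gr
}

.asDNAStringSet <- function(x) {
  if (is(x, "DNAStringSet")) seqs <- x
  else if (is(x, "DNAString")) seqs <- DNAStringSet(x)
  else if (is.character(x) && length(x) == 1L && file.exists(x))
    seqs <- readDNAStringSet(x)
  else seqs <- DNAStringSet(toupper(x))
  if (is.null(names(seqs)))
    names(seqs) <- paste0("seq", seq_along(seqs))
  # FASTA headers: keep the first word only
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Size-selection capture accounting
#'
#' Summarises a digest into per-end-class fragment counts and length
#' histograms, and computes how much of the genome is captured by a size
#' window: a fragment is captured when its end class is one of
#' \code{qualifyingClasses} (default \code{"PS"}, the amplifiable class of a
#' double digest) and its length falls inside the insert-scale window
#' (library window minus adapter offset), both ends inclusive. The capture
#' fraction divides captured bp by the total digested bp.
#'
#' @param fragments a \code{GRanges} from [digestGenome()].
#' @param window a [SizeWindow-class].
#' @param qualifyingClasses character vector of end classes.
#' @return a [DigestSummary-class].
#' @examples
#' cat <- enzymeCatalog()
#' fr <- digestGenome(paste0(strrep("A", 60), "CTGCAG", strrep("T", 200),
#'                           "CATG", strrep("A", 60)), cat$PstI, cat$NlaIII)
#' captureSummary(fr, sizeWindow(250, 400))
#' @export
captureSummary <- function(fragments, window, qualifyingClasses = "PS") {
  stopifnot(is(window, "SizeWindow"))
  iw <- insertWindow(window)
  if (iw[2] < 1)
    stop("invalid window: no positive insert length after adapter offset")
  allClasses <- c("PP", "PS", "SS", "END", "AMBIGUOUS")
  if (!all(qualifyingClasses %in% allClasses))
    stop("unknown end class in qualifyingClasses")
  if (length(fragments) == 0L) {
    return(new("DigestSummary",
               classCounts = stats::setNames(integer(5L), allClasses),
               lengthHist = data.frame(endClass = character(),
                                       length = integer(),
                                       count = integer()),
               capturedBp = 0, genomeBp = 0, captureFraction = 0,
               window = window,
               qualifyingClasses = qualifyingClasses))
  }
  cls <- factor(mcols(fragments)$endClass, levels = allClasses)
  w <- width(fragments)
  counts <- as.integer(table(cls))
  names(counts) <- allClasses
  hist <- as.data.frame(table(endClass = cls, length = w),
                        stringsAsFactors = FALSE)
  hist <- hist[hist$Freq > 0L, ]
  hist <- data.frame(endClass = as.character(hist$endClass),
                     length = as.integer(as.character(hist$length)),
                     count = as.integer(hist$Freq))
  hist <- hist[order(hist$endClass, hist$length), ]
  rownames(hist) <- NULL
  genomeBp <- sum(as.numeric(w))
  inWin <- as.character(cls) %in% qualifyingClasses &
    w >= max(iw[1], 1) & w <= iw[2]
  capturedBp <- sum(as.numeric(w[inWin]))
  new("DigestSummary",
      classCounts = counts, lengthHist = hist,
      capturedBp = capturedBp, genomeBp = genomeBp,
      captureFraction = if (genomeBp > 0) capturedBp / genomeBp else 0,
      window = window, qualifyingClasses = qualifyingClasses)
}

#' @describeIn DigestSummary-class the capture fraction in [0, 1].
#' @export
setMethod("captureFraction", "DigestSummary", function(x) x@captureFraction)

#' @describeIn DigestSummary-class captured bp in the window.
#' @export
setMethod("capturedBp", "DigestSummary", function(x) x@capturedBp)

#' @describeIn DigestSummary-class named fragment counts per end class.
#' @export
setMethod("endClassCounts", "DigestSummary", function(x) x@classCounts)

#' @describeIn DigestSummary-class fragment-length histogram per end class.
#' @export
setMethod("lengthHistogram", "DigestSummary", function(x) x@lengthHist)

#' @describeIn DigestSummary-class display.
#' @param object a [DigestSummary-class].
#' @export
setMethod("show", "DigestSummary", function(object) {
  cat("DigestSummary\n")
  cat("  fragments:",
      paste(sprintf("%s=%d", names(object@classCounts), object@classCounts),
            collapse = " "), "\n")
  iw <- insertWindow(object@window)
  cat(sprintf("  window: %g-%g library bp (insert %g-%g), classes {%s}\n",
              object@window@minLibrary, object@window@maxLibrary,
              iw[1], iw[2], paste(object@qualifyingClasses, collapse = ",")))
  cat(sprintf("  captured: %.0f / %.0f bp (%.4f%%)\n",
              object@capturedBp, object@genomeBp,
              100 * object@captureFraction))
})
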