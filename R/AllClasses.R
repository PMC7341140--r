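#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

.IUPAC <- c("A","C","G","T","R","Y","S","W","K","M","B","D","H","V","N")

#' Restriction enzyme
#'
#' An S4 container for a type II restriction enzyme as used in ddGBS library
#' design: its IUPAC recognition sequence, the top-strand cut offset (bp from
#' the 5' end of the recognition site to the cut point), the overhang length
#' left after cleavage (0 for blunt cutters), and the selection-relevant
#' flags (methylation sensitivity, reaction-buffer compatibility, incubation
#' temperature).
#'
#' For a palindromic enzyme the overhang length equals
#' \code{abs(2 * cutOffset - nchar(recognition))}; this is enforced by the
#' validity method.
#'
#' @slot name single character, e.g. \code{"PstI"}.
#' @slot recognition recognition sequence over the IUPAC alphabet.
#' @slot cutOffset integer, 0 to \code{nchar(recognition)}.
#' @slot overhangLen integer overhang length in bp; 0 means blunt.
#' @slot methylationSensitive logical.
#' @slot bufferCompatible logical; compatible with the digestion buffer used
#'   for the primary enzyme.
#' @slot incubationTemp numeric, degrees Celsius.
#'
#' @seealso [restrictionEnzyme()], [enzymeCatalog()]
#' @examples
#' restrictionEnzyme("PstI", "CTGCAG", cutOffset = 5, overhangLen = 4)
#' @export
setClass("RestrictionEnzyme",
  representation(
    name = "character",
    recognition = "character",
    cutOffset = "integer",
    overhangLen = "integer",
    methylationSensitive = "logical",
    bufferCompatible = "logical",
    incubationTemp = "numeric"
  )
)

setValidity("RestrictionEnzyme", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  rec <- object@recognition
  if (length(rec) != 1L || !nzchar(rec)) {
    msg <- c(msg, "recognition sequence must be non-empty")
  } else if (!all(strsplit(toupper(rec), "")[[1]] %in% .IUPAC)) {
    msg <- c(msg, "recognition sequence contains non-IUPAC characters")
  } else {
    if (length(object@cutOffset) != 1L || is.na(object@cutOffset) ||
        object@cutOffset < 0L || object@cutOffset > nchar(rec))
      msg <- c(msg, "cutOffset must lie within [0, nchar(recognition)]")
    if (isPalindromicRecognition(rec) &&
        length(object@cutOffset) == 1L && !is.na(object@cutOffset) &&
        object@cutOffset <= nchar(rec) && object@cutOffset >= 0L &&
        object@overhangLen != abs(2L * object@cutOffset - nchar(rec)))
      msg <- c(msg,
        "overhangLen inconsistent with cutOffset for a palindromic site")
  }
  if (object@overhangLen < 0L)
    msg <- c(msg, "overhangLen must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Size-selection window
#'
#' A library-scale size-selection window as realised on a gel-based size
#' selector. The window is stated on the \emph{library} scale (insert plus
#' ligated adapters and primers); \code{adapterOffset} is the number of bp the
#' adapters and primers add, so the corresponding insert window is
#' \code{[minLibrary - adapterOffset, maxLibrary - adapterOffset]}, both ends
#' inclusive.
#'
#' @slot minLibrary,maxLibrary inclusive library-molecule bounds in bp.
#' @slot adapterOffset bp added by adapters + primers (default 125).
#'
#' @seealso [sizeWindow()], [insertWindow()]
#' @export
setClass("SizeWindow",
  representation(
    minLibrary = "numeric",
    maxLibrary = "numeric",
    adapterOffset = "numeric"
  )
)

setValidity("SizeWindow", function(object) {
  msg <- character()
  if (object@minLibrary > object@maxLibrary)
    msg <- c(msg, "minLibrary must be <= maxLibrary")
  if (object@adapterOffset < 0)
    msg <- c(msg, "adapterOffset must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Digest capture summary
#'
#' Per-end-class fragment counts and length histograms for an in silico
#' digest, together with the capture accounting for one size-selection
#' window: \code{capturedBp} is the total length of fragments whose end
#' classes qualify and whose (insert-scale) length falls inside the window;
#' \code{captureFraction} divides by the total digested genome length.
#'
#' @slot classCounts named integer vector of fragment counts per end class
#'   (\code{PP}, \code{PS}, \code{SS}, \code{END}, \code{AMBIGUOUS}).
#' @slot lengthHist data.frame with columns \code{endClass}, \code{length},
#'   \code{count}.
#' @slot capturedBp,genomeBp numeric bp totals.
#' @slot captureFraction \code{capturedBp / genomeBp}.
#' @slot window the [SizeWindow-class] used.
#' @slot qualifyingClasses character, end classes counted as capturable.
#' @export
setClass("DigestSummary",
  representation(
    classCounts = "integer",
    lengthHist = "data.frame",
    capturedBp = "numeric",
    genomeBp = "numeric",
    captureFraction = "numeric",
    window = "SizeWindow",
    qualifyingClasses = "character"
  )
)

setValidity("DigestSummary", function(object) {
  msg <- character()
  h <- object@lengthHist
  if (nrow(h) && abs(sum(as.numeric(h$length) * h$count) - object@genomeBp) > 0.5)
    msg <- c(msg, "length histogram does not account for genomeBp")
  if (object@captureFraction < 0 || object@captureFraction > 1)
    msg <- c(msg, "captureFraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' In-line barcode table
#'
#' Sample-to-barcode assignments for demultiplexing, plus the enzyme cut-site
#' residual every genuine read must carry immediately after its barcode
#' (\code{"TGCAG"} for PstI libraries). Validity requires unique sample ids,
#' unique barcodes, and that no barcode can be mistaken for another barcode
#' followed by the start of the residual (which would make assignment
#' ambiguous for error-free reads).
#'
#' @slot sampleId character vector.
#' @slot barcode character vector of 4-8 bp DNA barcodes, parallel to
#'   \code{sampleId}.
#' @slot residual expected cut-site residual sequence.
#'
#' @seealso [barcodeTable()], [demultiplexReads()]
#' @export
setClass("BarcodeTable",
  representation(
    sampleId = "character",
    barcode = "character",
    residual = "character"
  )
)

setValidity("BarcodeTable", function(object) {
  msg <- character()
  if (length(object@sampleId) != length(object@barcode))
    msg <- c(msg, "sampleId and barcode must have equal length")
  if (anyDuplicated(object@sampleId))
    msg <- c(msg, "sample ids must be unique")
  if (anyDuplicated(object@barcode))
    msg <- c(msg, "barcodes must be unique")
  bc <- toupper(object@barcode)
  if (length(bc) && !all(grepl("^[ACGT]+$", bc)))
    msg <- c(msg, "barcodes must be plain ACGT sequences")
  if (length(object@residual) != 1L || !grepl("^[ACGT]*$", object@residual))
    msg <- c(msg, "residual must be a single ACGT string")
  # a shorter barcode + leading residual bases must never spell out a longer
  # barcode, otherwise error-free reads are inherently ambiguous
  res <- object@residual
  for (i in seq_along(bc)) {
    ext <- paste0(bc[i], res)
    clash <- bc[nchar(bc) > nchar(bc[i]) & startsWith(ext, bc)]
    if (length(clash))
      msg <- c(msg, sprintf(
        "barcode '%s' plus residual masks longer barcode(s): %s",
        bc[i], paste(clash, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Demultiplexing result
#'
#' Book-keeping for one demultiplexing run: per-sample assigned read counts
#' and the three discard categories. Counts always satisfy
#' \code{sum(sampleCounts) + unassigned + noResidual + ambiguous == total}.
#'
#' @slot sampleCounts named integer vector of assigned reads per sample.
#' @slot unassigned reads with no barcode within the mismatch tolerance.
#' @slot noResidual reads whose matched barcode is not followed by the exact
#'   cut-site residual.
#' @slot ambiguous reads tied between two barcodes at the minimal distance.
#' @slot total input reads.
#' @slot reads optional list of per-sample
#'   \code{QualityScaledDNAStringSet}s (barcode trimmed, residual retained).
#' @export
setClass("DemuxResult",
  representation(
    sampleCounts = "integer",
    unassigned = "integer",
    noResidual = "integer",
    ambiguous = "integer",
    total = "integer",
    reads = "list"
  )
)

setValidity("DemuxResult", function(object) {
  tot <- sum(object@sampleCounts) + object@unassigned +
    object@noResidual + object@ambiguous
  if (tot != object@total)
    "read conservation violated: categories do not sum to total"
  else TRUE
})

#' Biallelic genotype calls
#'
#' A \linkS4class{SummarizedExperiment} holding a sites-by-samples matrix of
#' biallelic genotype calls coded as alt-allele counts (0 = hom ref, 1 = het,
#' 2 = hom alt, \code{NA} = missing) in the \code{"calls"} assay, with site
#' metadata (\code{chrom}, \code{pos}, \code{ref}, \code{alt}, optional
#' \code{known}) in \code{rowData}. Minor allele frequency and call rate are
#' always derived from the calls via [siteMAF()] and [siteCallRate()], never
#' stored stale.
#'
#' @seealso [genotypeCalls()], [readVcfBiallelic()], [filterSites()]
#' @export
setClass("GenotypeCalls", contains = "SummarizedExperiment")

setValidity("GenotypeCalls", function(object) {
  msg <- character()
  if (!"calls" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'calls' is required")
  else {
    m <- SummarizedExperiment::assay(object, "calls")
    if (!all(m %in% c(0L, 1L, 2L, NA)))
      msg <- c(msg, "calls must be in {0, 1, 2, NA}")
  }
  rd <- SummarizedExperiment::rowData(object)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% colnames(rd)))
    msg <- c(msg, paste("rowData must contain:", paste(need, collapse = ", ")))
  else if (nrow(rd) && any(rd$ref == rd$alt))
    msg <- c(msg, "ref and alt alleles must differ")
  if (length(msg)) msg else TRUE
})

#' Trio Mendelian-error report
#'
#' Output of [mendelScan()]: per-site counts of complete, informative and
#' error trios, the observed error rate (errors / informative trios) and the
#' model-expected informative fraction \code{1 - (1 - 2p(1-p))^3}; and
#' per-sample error totals with each trio error attributed to the offspring.
#'
#' @slot perSite data.frame: \code{chrom}, \code{pos}, \code{maf},
#'   \code{nComplete}, \code{nInformative}, \code{nErrors}, \code{errorRate},
#'   \code{expectedInformative}.
#' @slot perSample data.frame: \code{sample}, \code{nTrios}, \code{nErrors},
#'   \code{errorRate} (per informative trio-site).
#' @slot nTrios number of resolvable trios scanned.
#' @export
setClass("MendelReport",
  representation(
    perSite = "data.frame",
    perSample = "data.frame",
    nTrios = "integer"
  )
)

setValidity("MendelReport", function(object) {
  s <- object@perSite
  if (nrow(s) && any(s$nErrors > s$nInformative))
    "per-site error count exceeds informative-trio count"
  else TRUE
})

#' Sex-check report
#'
#' Per-sample X-chromosome read fractions with inferred sex (female iff the
#' fraction exceeds the threshold, default 3\% of mapped reads), the recorded
#' pedigree sex, and a mismatch flag.
#'
#' @slot table data.frame: \code{sample}, \code{xReads}, \code{totalReads},
#'   \code{xFraction}, \code{inferredSex}, \code{recordedSex},
#'   \code{mismatch}, \code{undefined}.
#' @slot threshold numeric X-fraction cutoff.
#' @export
setClass("SexCheckReport",
  representation(table = "data.frame", threshold = "numeric")
)

#' Callset concordance report
#'
#' Genotype discordance between two callsets over sites matched on
#' (chrom, pos) with identical or swapped ref/alt alleles (swapped sites have
#' their calls flipped 0 <-> 2; A/T and C/G sites needing a swap are excluded
#' as strand-ambiguous). Discordance is computed only over jointly
#' non-missing calls.
#'
#' @slot overall overall discordance rate.
#' @slot nSitesCompared,nAlleleMismatch,nAmbiguousExcluded integers.
#' @slot perSample data.frame: \code{sample}, \code{nCompared},
#'   \code{nDiscordant}, \code{discordance}.
#' @slot perSite data.frame: \code{chrom}, \code{pos}, \code{nCompared},
#'   \code{nDiscordant}, \code{discordance}.
#' @slot thresholdCurve data.frame: \code{threshold}, \code{nSites} with
#'   per-site discordance <= threshold.
#' @export
setClass("ConcordanceReport",
  representation(
    overall = "numeric",
    nSitesCompared = "integer",
    nAlleleMismatch = "integer",
    nAmbiguousExcluded = "integer",
    perSample = "data.frame",
    perSite = "data.frame",
    thresholdCurve = "data.frame"
  )
)
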