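#' @importFrom Biostrings QualityScaledDNAStringSet PhredQuality quality
#'   readQualityScaledDNAStringSet writeQualityScaledXStringSet
#'   neditStartingAt
#' @importFrom IRanges narrow
NULL

#' Construct a barcode table
#'
#' @param sampleId sample identifiers.
#' @param barcode in-line barcodes (4-8 bp DNA), parallel to
#'   \code{sampleId}.
#' @param residual expected enzyme cut-site residual following the barcode
#'   in every genuine read; default \code{"TGCAG"} (PstI).
#' @return a [BarcodeTable-class].
#' @examples
#' barcodeTable(c("s1", "s2"), c("ACGT", "TTAGGC"))
#' @export
barcodeTable <- function(sampleId, barcode, residual = "TGCAG") {
  new("BarcodeTable", sampleId = as.character(sampleId),
      barcode = toupper(as.character(barcode)),
      residual = toupper(residual))
}

#' Read a barcode table from TSV
#'
#' Expects columns \code{sample_id} and \code{barcode} (header required).
#'
#' @param path TSV path.
#' @param residual see [barcodeTable()].
#' @return a [BarcodeTable-class].
#' @export
readBarcodeTable <- function(path, residual = "TGCAG") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("sample_id", "barcode") %in% colnames(tab)))
    stop("barcode table must have columns 'sample_id' and 'barcode'")
  barcodeTable(tab$sample_id, tab$barcode, residual)
}

#' @describeIn BarcodeTable-class display.
#' @param object a [BarcodeTable-class].
#' @export
setMethod("show", "BarcodeTable", function(object) {
  cat(sprintf("BarcodeTable: %d samples, barcodes %d-%d bp, residual %s\n",
              length(object@sampleId),
              if (length(object@barcode)) min(nchar(object@barcode)) else 0L,
              if (length(object@barcode)) max(nchar(object@barcode)) else 0L,
              object@residual))
})

#' Demultiplex in-line barcoded GBS reads
#'
#' Splits single-end reads of layout \code{[barcode][residual][insert]} by
#' their in-line barcode. A read is assigned to the unique barcode at
#' minimal Hamming distance over the barcode-length prefix, provided that
#' distance is at most \code{maxMismatch}; candidates are compared by
#' (distance, then longer barcode wins) and reads still tied after both
#' criteria are counted \code{ambiguous} and discarded. Assigned reads must
#' then carry the exact cut-site residual immediately after the matched
#' barcode — the residual doubles as a ligation check, so no mismatch is
#' tolerated there; failures are counted \code{noResidual} and discarded.
#' Emitted reads have the barcode trimmed and the residual retained.
#'
#' @param reads a \code{QualityScaledDNAStringSet}, or a path to a FASTQ
#'   file (gzip transparent).
#' @param table a [BarcodeTable-class].
#' @param maxMismatch maximum Hamming distance tolerated in the barcode;
#'   default 1.
#' @param outDir if non-NULL, per-sample FASTQ files
#'   (\code{<sample>.fastq}) are written there and read sets are not kept in
#'   memory.
#' @param keepReads keep per-sample reads in the result (default TRUE when
#'   \code{outDir} is NULL).
#' @return a [DemuxResult-class].
#' @examples
#' bt <- barcodeTable(c("s1", "s2"), c("ACGT", "GGCCA"))
#' rd <- Biostrings::QualityScaledDNAStringSet(
#'   Biostrings::DNAStringSet(c(r1 = "ACGTTGCAGAAAATTTT")),
#'   Biostrings::PhredQuality(strrep("I", 17)))
#' sampleCounts(demultiplexReads(rd, bt))
#' @export
demultiplexReads <- function(reads, table, maxMismatch = 1L,
                             outDir = NULL, keepReads = is.null(outDir)) {
  stopifnot(is(table, "BarcodeTable"))
  validObject(table)
  if (is.character(reads)) reads <- readFastq(reads)
  stopifnot(is(reads, "QualityScaledDNAStringSet"))
  n <- length(reads)
  bc <- table@barcode
  res <- table@residual
  nb <- length(bc)
  wid <- width(reads)
  # mismatch count of each barcode against each read's prefix
  dist <- matrix(NA_integer_, nrow = n, ncol = nb)
  if (n > 0L) for (j in seq_len(nb)) {
    d <- neditStartingAt(DNAString(bc[j]), reads, starting.at = 1L,
                         with.indels = FALSE)
    d[wid < nchar(bc[j])] <- NA_integer_
    dist[, j] <- d
  }
  assignment <- rep(NA_integer_, n)
  category <- rep("unassigned", n)
  if (n > 0L) {
    minDist <- suppressWarnings(
      apply(dist, 1L, min, na.rm = TRUE))
    minDist[!is.finite(minDist)] <- NA_integer_
    lens <- nchar(bc)
    for (i in seq_len(n)) {
      md <- minDist[i]
      if (is.na(md) || md > maxMismatch) next
      cand <- which(!is.na(dist[i, ]) & dist[i, ] == md)
      best <- cand[lens[cand] == max(lens[cand])]
      if (length(best) > 1L) { category[i] <- "ambiguous"; next }
      L <- lens[best]
      ok <- wid[i] >= L + nchar(res) &&
        as.character(narrow(reads[i], L + 1L,
                            L + nchar(res))[[1]]) == res
      if (!ok) { category[i] <- "no_residual"; next }
      category[i] <- "assigned"
      assignment[i] <- best
    }
  }
  counts <- integer(nb)
  names(counts) <- table@sampleId
  if (any(category == "assigned")) {
    tb <- table(assignment[category == "assigned"])
    counts[as.integer(names(tb))] <- as.integer(tb)
  }
  outReads <- list()
  emit <- !is.null(outDir) || keepReads
  if (emit) {
    if (!is.null(outDir) && !dir.exists(outDir))
      dir.create(outDir, recursive = TRUE)
    for (j in seq_len(nb)) {
      idx <- which(!is.na(assignment) & assignment == j)
      trimmed <- narrow(reads[idx], start = nchar(bc[j]) + 1L)
      S4Vectors::mcols(trimmed) <- NULL
      if (!is.null(outDir))
        writeQualityScaledXStringSet(
          trimmed, file.path(outDir, paste0(table@sampleId[j], ".fastq")))
      if (keepReads) outReads[[table@sampleId[j]]] <- trimmed
    }
  }
  new("DemuxResult",
      sampleCounts = counts,
      unassigned = sum(category == "unassigned"),
      noResidual = sum(category == "no_residual"),
      ambiguous = sum(category == "ambiguous"),
      total = n,
      reads = outReads)
}

#' @describeIn DemuxResult-class named per-sample assigned-read counts.
#' @export
setMethod("sampleCounts", "DemuxResult", function(x) x@sampleCounts)

#' @describeIn DemuxResult-class display.
#' @param object a [DemuxResult-class].
#' @export
setMethod("show", "DemuxResult", function(object) {
  cat(sprintf(
    "DemuxResult: %d reads -> %d assigned / %d unassigned / %d no-residual / %d ambiguous\n",
    object@total, sum(object@sampleCounts), object@unassigned,
    object@noResidual, object@ambiguous))
})

#' Per-sample read-count threshold
#'
#' Flags samples whose assigned read count falls below the minimum required
#' for acceptable genotype missingness. The boundary is inclusive: a sample
#' with exactly \code{minReads} reads passes.
#'
#' @param result a [DemuxResult-class].
#' @param minReads minimum assigned reads per sample; default 2,000,000.
#' @return data.frame with columns \code{sample}, \code{reads},
#'   \code{pass}; failing samples can be read off with
#'   \code{subset(x, !pass)}.
#' @export
applySampleThreshold <- function(result, minReads = 2e6) {
  stopifnot(is(result, "DemuxResult"))
  data.frame(sample = names(result@sampleCounts),
             reads = as.integer(result@sampleCounts),
             pass = result@sampleCounts >= minReads,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' 3' quality trimming
#'
#' Trims low-quality 3' ends with the running-sum rule used by standard
#' read trimmers: walking in from the 3' end, the cumulative sum of
#' \code{(threshold - quality)} is tracked and the read is cut before the
#' suffix that maximises this sum (the longest such suffix when several tie);
#' if no suffix has a positive sum the read is untouched. Reads shorter than
#' \code{minLength} after trimming are dropped and counted.
#'
#' @param reads a \code{QualityScaledDNAStringSet} (phred+33) or FASTQ path.
#' @param qualThreshold phred threshold, default 20.
#' @param minLength minimum retained read length, default 25; the boundary
#'   is inclusive (a 25 bp read survives).
#' @return list with elements \code{reads} (trimmed
#'   \code{QualityScaledDNAStringSet}), \code{nDropped},
#'   \code{nBasesTrimmed}.
#' @export
qualityTrim <- function(reads, qualThreshold = 20L, minLength = 25L) {
  if (is.character(reads)) reads <- readFastq(reads)
  stopifnot(is(reads, "QualityScaledDNAStringSet"))
  quals <- as(quality(reads), "IntegerList")
  wid <- width(reads)
  if (any(lengths(quals) != wid))
    stop("quality/sequence length mismatch")
  keepLen <- vapply(seq_along(reads), function(i) {
    q <- quals[[i]]
    n <- length(q)
    if (n == 0L) return(0L)
    s <- cumsum(qualThreshold - rev(q))  # suffix sums, 3' inward
    m <- max(s)
    if (m <= 0) return(n)
    n - max(which(s == m))               # longest maximising suffix
  }, integer(1L))
  nBasesTrimmed <- sum(wid - keepLen)
  keep <- keepLen >= minLength
  trimmed <- narrow(reads[keep], start = 1L, end = keepLen[keep])
  list(reads = trimmed,
       nDropped = sum(!keep),
       nBasesTrimmed = nBasesTrimmed)
}
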