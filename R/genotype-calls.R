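#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData rowData<-
NULL

#' Construct a GenotypeCalls object
#'
#' @param calls integer matrix, sites x samples, values in
#'   \code{{0, 1, 2, NA}} counting alt alleles.
#' @param chrom,pos,ref,alt site metadata vectors (pos is 1-based).
#' @param known optional logical vector: site present in a reference list of
#'   previously identified variants.
#' @param samples sample ids; defaults to \code{colnames(calls)}.
#' @return a [GenotypeCalls-class].
#' @examples
#' gm <- genotypeCalls(matrix(c(0L, 1L, 2L, NA), 2, 2,
#'                            dimnames = list(NULL, c("a", "b"))),
#'                     chrom = c("1", "1"), pos = c(100L, 200L),
#'                     ref = c("A", "C"), alt = c("G", "T"))
#' siteMAF(gm)
#' @export
genotypeCalls <- function(calls, chrom, pos, ref, alt, known = NA,
                          samples = colnames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(samples)) samples <- paste0("sample", seq_len(ncol(calls)))
  colnames(calls) <- samples
  rd <- DataFrame(chrom = as.character(chrom), pos = as.integer(pos),
                  ref = toupper(as.character(ref)),
                  alt = toupper(as.character(alt)),
                  known = rep_len(known, nrow(calls)))
  se <- SummarizedExperiment(assays = list(calls = calls), rowData = rd)
  rownames(se) <- paste0(rd$chrom, ":", rd$pos)
  obj <- new("GenotypeCalls", se)
  validObject(obj)
  obj
}

#' @describeIn GenotypeCalls-class the sites-by-samples call matrix.
#' @export
setMethod("calls", "GenotypeCalls", function(x) assay(x, "calls"))

#' @describeIn GenotypeCalls-class site metadata as a data.frame.
#' @export
setMethod("siteInfo", "GenotypeCalls",
          function(x) as.data.frame(rowData(x)))

#' @describeIn GenotypeCalls-class per-site minor allele frequency (folded
#'   alt-allele frequency), computed from the calls; \code{NA} where no
#'   genotype is called.
#' @export
setMethod("siteMAF", "GenotypeCalls", function(x) {
  m <- assay(x, "calls")
  nCalled <- rowSums(!is.na(m))
  p <- rowSums(m, na.rm = TRUE) / (2 * nCalled)
  p[nCalled == 0L] <- NA_real_
  pmin(p, 1 - p)
})

#' @describeIn GenotypeCalls-class per-site fraction of non-missing calls.
#' @export
setMethod("siteCallRate", "GenotypeCalls", function(x) {
  m <- assay(x, "calls")
  rowMeans(!is.na(m))
})

#' @describeIn GenotypeCalls-class display.
#' @param object a [GenotypeCalls-class].
#' @export
setMethod("show", "GenotypeCalls", function(object) {
  m <- assay(object, "calls")
  cat(sprintf("GenotypeCalls: %d sites x %d samples (%.1f%% called)\n",
              nrow(m), ncol(m),
              if (length(m)) 100 * mean(!is.na(m)) else 0))
})

#' Per-site genotype counts
#'
#' Counts hom-ref, het and hom-alt calls per site; the triple consumed by
#' [hweExactTest()].
#'
#' @param gm a [GenotypeCalls-class].
#' @return integer matrix with columns \code{nHomRef}, \code{nHet},
#'   \code{nHomAlt}.
#' @export
genotypeCounts <- function(gm) {
  m <- calls(gm)
  cbind(nHomRef = rowSums(m == 0L, na.rm = TRUE),
        nHet = rowSums(m == 1L, na.rm = TRUE),
        nHomAlt = rowSums(m == 2L, na.rm = TRUE))
}
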