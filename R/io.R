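#' @importFrom VariantAnnotation readVcf geno ref alt
#' @importFrom SummarizedExperiment rowRanges
#' @importFrom GenomicRanges seqnames
NULL

#' Read sequences from FASTA
#'
#' Thin wrapper over \code{Biostrings::readDNAStringSet} (gzip
#' transparent); sequence names are truncated at the first whitespace, as
#' aligners do.
#'
#' @param path FASTA path.
#' @return a \code{DNAStringSet}.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  .asDNAStringSet(readDNAStringSet(path))
}

#' Read reads from FASTQ
#'
#' @param path FASTQ path (phred+33 qualities; gzip transparent).
#' @return a \code{QualityScaledDNAStringSet}.
#' @export
readFastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  # Biostrings parks the qualities in mcols while parsing and warns when
  # they are moved into the quality slot; that warning is noise here
  withCallingHandlers(
    readQualityScaledDNAStringSet(path, quality.scoring = "phred"),
    warning = function(w) {
      if (grepl("metadata columns on input DNAStringSet", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

#' Read biallelic SNP genotypes from VCF
#'
#' Parses a VCF with \code{VariantAnnotation::readVcf}, keeps only
#' biallelic single-nucleotide records (multiallelic and indel records are
#' skipped and counted), and converts GT fields into alt-allele counts.
#' \code{"./."}, half-missing and \code{"."} genotypes all become missing.
#' Positions stay 1-based as in the VCF.
#'
#' @param path VCF path (plain or bgzipped).
#' @return a [GenotypeCalls-class]; the number of skipped records is
#'   available as \code{metadata(x)$skippedRecords}.
#' @export
readVcfBiallelic <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- readVcf(path)
  refs <- as.character(ref(v))
  nAlt <- lengths(alt(v))
  keep <- nAlt == 1L & nchar(refs) == 1L
  alts <- rep(NA_character_, length(v))
  alts[keep] <- as.character(unlist(alt(v)[keep]))
  keep <- keep & !is.na(alts) & nchar(alts) == 1L &
    alts %in% c("A", "C", "G", "T") & refs %in% c("A", "C", "G", "T")
  nSkipped <- sum(!keep)
  v <- v[keep, ]
  gt <- geno(v)$GT
  if (is.null(gt)) stop("VCF has no GT genotype field")
  m <- matrix(.gtToCode(gt), nrow(gt), ncol(gt),
              dimnames = dimnames(gt))
  rr <- rowRanges(v)
  gm <- genotypeCalls(m,
                      chrom = as.character(seqnames(rr)),
                      pos = start(rr),
                      ref = refs[keep], alt = alts[keep],
                      samples = colnames(gt))
  metadata(gm)$skippedRecords <- nSkipped
  gm
}

## GT strings -> alt-allele counts; any missing allele -> NA
.gtToCode <- function(gt) {
  g <- gsub("\\|", "/", as.character(gt))
  code <- rep(NA_integer_, length(g))
  code[g %in% c("0/0", "0")] <- 0L
  code[g %in% c("0/1", "1/0")] <- 1L
  code[g %in% c("1/1", "1")] <- 2L
  code
}

#' Write biallelic genotypes as a minimal VCF
#'
#' Emits a deterministic VCFv4.2 file with GT-only FORMAT, suitable for
#' interchange with standard tools and for lossless round-trips through
#' [readVcfBiallelic()].
#'
#' @param gm a [GenotypeCalls-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeVcfBiallelic <- function(gm, path) {
  stopifnot(is(gm, "GenotypeCalls"))
  si <- siteInfo(gm)
  m <- calls(gm)
  gtmap <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(m), ncol(m))
  gt[!is.na(m)] <- gtmap[m[!is.na(m)] + 1L]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", colnames(m)),
                     collapse = "\t")), con)
  body <- cbind(si$chrom, si$pos, ".", si$ref, si$alt, ".", ".", ".", "GT",
                gt)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a FAM/PED-style pedigree
#'
#' Reads a whitespace-separated, headerless pedigree file with the PLINK
#' FAM layout (family id, individual id, sire, dam, sex, [phenotype]).
#' \code{"0"} parents become \code{NA}; sex codes 1/2 become
#' \code{"M"}/\code{"F"}.
#'
#' @param path file path.
#' @return data.frame with columns \code{fid}, \code{id}, \code{sire},
#'   \code{dam}, \code{sex}.
#' @export
readFam <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 5L)
    stop("pedigree file needs at least 5 columns (fid id sire dam sex)")
  sex <- as.character(tab[[5]])
  sex[sex == "1"] <- "M"; sex[sex == "2"] <- "F"
  sex[!sex %in% c("M", "F")] <- NA_character_
  out <- data.frame(fid = as.character(tab[[1]]),
                    id = as.character(tab[[2]]),
                    sire = as.character(tab[[3]]),
                    dam = as.character(tab[[4]]),
                    sex = sex, stringsAsFactors = FALSE)
  out$sire[out$sire == "0"] <- NA_character_
  out$dam[out$dam == "0"] <- NA_character_
  out
}

#' Read idxstats-style read-count tables
#'
#' Each input file holds the four \code{samtools idxstats} columns (contig,
#' length, mapped, unmapped) for one sample; the sample id is the file name
#' without extension unless \code{sampleIds} is given. Multiple files are
#' stacked into the long format consumed by [sexInfer()].
#'
#' @param paths one or more file paths.
#' @param sampleIds optional sample ids parallel to \code{paths}.
#' @return data.frame with columns \code{sample}, \code{contig},
#'   \code{length}, \code{mapped}, \code{unmapped}.
#' @export
readIdxstats <- function(paths, sampleIds = NULL) {
  if (is.null(sampleIds))
    sampleIds <- sub("\\.[^.]*$", "", basename(paths))
  stopifnot(length(sampleIds) == length(paths))
  rows <- lapply(seq_along(paths), function(i) {
    if (!file.exists(paths[i])) stop("file not found: ", paths[i])
    tab <- utils::read.table(paths[i], header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 4L)
      stop("idxstats file needs 4 columns: ", paths[i])
    data.frame(sample = sampleIds[i], contig = as.character(tab[[1]]),
               length = tab[[2]], mapped = tab[[3]], unmapped = tab[[4]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write digest fragments as BED
#'
#' BED uses 0-based half-open coordinates. Columns:
#' \code{seq, start, end, leftEnd, rightEnd, endClass}.
#'
#' @param fragments \code{GRanges} from [digestGenome()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFragmentsBed <- function(fragments, path) {
  df <- data.frame(seq = as.character(seqnames(fragments)),
                   start = start(fragments) - 1L,
                   end = end(fragments),
                   leftEnd = mcols(fragments)$leftEnd,
                   rightEnd = mcols(fragments)$rightEnd,
                   endClass = mcols(fragments)$endClass)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.fmtFrac <- function(x) formatC(x, digits = 6, format = "f")

#' Write a report object as TSV
#'
#' Writes the tabular core of a ddGBStools result with a stable column
#' order and fixed numeric formatting (fractions at 6 decimals), so
#' re-running on identical input reproduces the file byte for byte.
#'
#' @param x a [DigestSummary-class], [DemuxResult-class],
#'   [MendelReport-class], [SexCheckReport-class] or
#'   [ConcordanceReport-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeReport <- function(x, path) {
  df <- reportTable(x)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], .fmtFrac)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tabular view of a report object
#'
#' @param x a report object (see [writeReport()]).
#' @return a data.frame.
#' @export
reportTable <- function(x) {
  if (is(x, "DigestSummary")) {
    h <- lengthHistogram(x)
    data.frame(endClass = names(endClassCounts(x)),
               nFragments = as.integer(endClassCounts(x)),
               bp = vapply(names(endClassCounts(x)), function(cl)
                 sum(as.numeric(h$length[h$endClass == cl]) *
                       h$count[h$endClass == cl]), numeric(1)),
               capturedBp = capturedBp(x),
               genomeBp = x@genomeBp,
               captureFraction = captureFraction(x),
               row.names = NULL)
  } else if (is(x, "DemuxResult")) {
    rbind(data.frame(sample = names(sampleCounts(x)),
                     category = "assigned",
                     reads = as.integer(sampleCounts(x))),
          data.frame(sample = NA_character_,
                     category = c("unassigned", "no_residual", "ambiguous"),
                     reads = c(x@unassigned, x@noResidual, x@ambiguous)))
  } else if (is(x, "MendelReport")) {
    perSite(x)
  } else if (is(x, "SexCheckReport")) {
    perSample(x)
  } else if (is(x, "ConcordanceReport")) {
    perSite(x)
  } else stop("no tabular view for class ", class(x)[1])
}
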