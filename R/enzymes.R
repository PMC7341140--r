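#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   matchPattern reverseComplement
NULL

#' Test whether a recognition sequence is palindromic
#'
#' A restriction site is palindromic when it equals its own reverse
#' complement (IUPAC ambiguity codes are complemented symbolically, so
#' e.g. \code{"GRYC"} is palindromic too).
#'
#' @param recognition a recognition sequence (character).
#' @return logical.
#' @examples
#' isPalindromicRecognition("CTGCAG")  # TRUE
#' isPalindromicRecognition("GAATGC")  # FALSE
#' @export
isPalindromicRecognition <- function(recognition) {
  stopifnot(is.character(recognition), length(recognition) == 1L)
  s <- toupper(recognition)
  s == as.character(reverseComplement(DNAString(s)))
}

#' Construct a restriction enzyme
#'
#' @param name enzyme name, e.g. \code{"NlaIII"}.
#' @param recognition IUPAC recognition sequence.
#' @param cutOffset bp from the 5' end of the site to the top-strand cut.
#' @param overhangLen overhang length in bp (0 = blunt). Defaults to the
#'   palindromic relation \code{abs(2 * cutOffset - nchar(recognition))}.
#' @param methylationSensitive,bufferCompatible logical selection flags.
#' @param incubationTemp incubation temperature in degrees Celsius.
#' @return a [RestrictionEnzyme-class].
#' @examples
#' nla <- restrictionEnzyme("NlaIII", "CATG", cutOffset = 4)
#' overhangLength(nla)  # 4
#' @export
restrictionEnzyme <- function(name, recognition, cutOffset,
                              overhangLen = abs(2L * as.integer(cutOffset) -
                                                nchar(recognition)),
                              methylationSensitive = FALSE,
                              bufferCompatible = TRUE,
                              incubationTemp = 37) {
  if (!is.character(recognition) || length(recognition) != 1L ||
      !nzchar(recognition))
    stop("invalid enzyme: recognition sequence must be a non-empty string")
  new("RestrictionEnzyme",
      name = as.character(name),
      recognition = toupper(recognition),
      cutOffset = as.integer(cutOffset),
      overhangLen = as.integer(overhangLen),
      methylationSensitive = isTRUE(methylationSensitive),
      bufferCompatible = isTRUE(bufferCompatible),
      incubationTemp = as.numeric(incubationTemp))
}

#' @rdname RestrictionEnzyme-class
#' @param x a [RestrictionEnzyme-class].
#' @export
enzymeName <- function(x) x@name

#' @rdname RestrictionEnzyme-class
#' @export
recognitionSite <- function(x) x@recognition

#' @rdname RestrictionEnzyme-class
#' @export
cutOffset <- function(x) x@cutOffset

#' @rdname RestrictionEnzyme-class
#' @export
overhangLength <- function(x) x@overhangLen

#' Built-in enzyme catalog
#'
#' Loads a restriction-enzyme catalog from a tab-separated file with columns
#' \code{name}, \code{recognition}, \code{cut_offset}, \code{overhang_len},
#' \code{methylation_sensitive}, \code{buffer_compatible}, \code{temp}. With
#' no argument, the catalog shipped with the package is used: PstI plus the
#' seven candidate 4-cutters commonly considered as ddGBS secondary enzymes
#' (AluI, BfaI, DpnI, HaeIII, MluCI, MspI, NlaIII).
#'
#' @param path optional path to a catalog TSV.
#' @return named list of [RestrictionEnzyme-class] objects.
#' @examples
#' cat <- enzymeCatalog()
#' recognitionSite(cat$PstI)
#' @export
enzymeCatalog <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "enzymes.tsv", package = "ddGBStools",
                        mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("name", "recognition", "cut_offset", "overhang_len",
            "methylation_sensitive", "buffer_compatible", "temp")
  if (!all(need %in% colnames(tab)))
    stop("enzyme catalog must have columns: ", paste(need, collapse = ", "))
  enz <- lapply(seq_len(nrow(tab)), function(i)
    restrictionEnzyme(tab$name[i], tab$recognition[i], tab$cut_offset[i],
                      tab$overhang_len[i],
                      as.logical(tab$methylation_sensitive[i]),
                      as.logical(tab$buffer_compatible[i]),
                      tab$temp[i]))
  names(enz) <- tab$name
  enz
}

#' Scan a sequence for recognition sites
#'
#' Finds all occurrences (including overlapping ones) of an enzyme's
#' recognition sequence in a DNA sequence and returns their 0-based start
#' positions on the top strand. IUPAC ambiguity codes in the recognition
#' sequence are honoured; \code{N}s in the \emph{subject} never match, so
#' sites overlapping assembly gaps are not reported. Non-palindromic enzymes
#' are scanned on both strands; minus-strand hits are reported as top-strand
#' start coordinates, with a \code{"strand"} attribute on the result.
#'
#' @param sequence a \code{DNAString} or single character string.
#' @param enzyme a [RestrictionEnzyme-class].
#' @return sorted integer vector of 0-based site starts. For non-palindromic
#'   enzymes the vector carries a parallel \code{"strand"} attribute of
#'   \code{"+"}/\code{"-"}.
#' @examples
#' pst <- enzymeCatalog()$PstI
#' scanRecognitionSites("AACTGCAGG", pst)  # 2
#' @export
scanRecognitionSites <- function(sequence, enzyme) {
  stopifnot(is(enzyme, "RestrictionEnzyme"))
  validObject(enzyme)
  if (!nzchar(enzyme@recognition))
    stop("invalid enzyme: empty recognition sequence")
  subject <- if (is(sequence, "DNAString")) sequence
             else DNAString(toupper(as.character(sequence)))
  pat <- DNAString(enzyme@recognition)
  hits <- start(matchPattern(pat, subject, fixed = "subject")) - 1L
  if (isPalindromicRecognition(enzyme@recognition))
    return(sort(hits))
  rc <- reverseComplement(pat)
  minus <- start(matchPattern(rc, subject, fixed = "subject")) - 1L
  pos <- c(hits, minus)
  str <- c(rep("+", length(hits)), rep("-", length(minus)))
  o <- order(pos)
  out <- pos[o]
  attr(out, "strand") <- str[o]
  out
}

#' Convert recognition-site positions to cut coordinates
#'
#' Cut coordinates are 0-based between-base indices on the top strand:
#' coordinate \code{k} denotes the bond between base \code{k} and base
#' \code{k + 1} (0-based), so a fragment boundary at \code{k} splits the
#' sequence into \code{[0, k)} and \code{[k, len)}. For a plus-strand site at
#' \code{s} the cut falls at \code{s + cutOffset(enzyme)}; minus-strand sites
#' of non-palindromic enzymes cut at
#' \code{s + nchar(recognition) - cutOffset}. Coordinates at or outside the
#' sequence ends are dropped (they produce no internal boundary), and
#' duplicates are collapsed.
#'
#' @param sites 0-based site starts from [scanRecognitionSites()] (its
#'   \code{"strand"} attribute, if any, is used).
#' @param enzyme a [RestrictionEnzyme-class].
#' @param seqLength sequence length in bp, used to drop cuts at or beyond
#'   the end; \code{NA} disables the upper bound.
#' @return sorted integer vector of cut coordinates.
#' @examples
#' cutPositions(c(0L, 4L), enzymeCatalog()$NlaIII, seqLength = 8L)  # 4
#' @export
cutPositions <- function(sites, enzyme, seqLength = NA) {
  stopifnot(is(enzyme, "RestrictionEnzyme"))
  if (length(sites) == 0L) return(integer())
  strand <- attr(sites, "strand")
  off <- enzyme@cutOffset
  cuts <- if (is.null(strand)) as.integer(sites) + off
          else as.integer(sites) +
            ifelse(strand == "+", off, nchar(enzyme@recognition) - off)
  cuts <- cuts[cuts > 0L]
  if (!is.na(seqLength)) cuts <- cuts[cuts < as.integer(seqLength)]
  sort(unique(cuts))
}

#' @describeIn RestrictionEnzyme-class compact display.
#' @param object a [RestrictionEnzyme-class].
#' @export
setMethod("show", "RestrictionEnzyme", function(object) {
  cat(sprintf("RestrictionEnzyme %s: %s (cut %d, %s%s)\n",
              object@name, object@recognition, object@cutOffset,
              if (object@overhangLen == 0L) "blunt"
              else paste0(object@overhangLen, " nt overhang"),
              if (object@methylationSensitive) ", methylation-sensitive"
              else ""))
})
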