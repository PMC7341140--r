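## 27-configuration autosomal biallelic consistency table, indexed
## [offspring+1, sire+1, dam+1]. TRUE = consistent with Mendelian
## transmission (offspring draws one allele from each parent's genotype).
## Hardcoded constant; the test suite re-derives it by gamete enumeration.
.MENDEL_OK <- array(FALSE, dim = c(3L, 3L, 3L))
.MENDEL_OK[1, 1, 1] <- TRUE                     # AA x AA -> AA
.MENDEL_OK[c(1, 2), 1, 2] <- TRUE               # AA x AB -> AA, AB
.MENDEL_OK[2, 1, 3] <- TRUE                     # AA x BB -> AB
.MENDEL_OK[c(1, 2), 2, 1] <- TRUE               # AB x AA
.MENDEL_OK[c(1, 2, 3), 2, 2] <- TRUE            # AB x AB -> anything
.MENDEL_OK[c(2, 3), 2, 3] <- TRUE               # AB x BB
.MENDEL_OK[2, 3, 1] <- TRUE                     # BB x AA -> AB
.MENDEL_OK[c(2, 3), 3, 2] <- TRUE               # BB x AB
.MENDEL_OK[3, 3, 3] <- TRUE                     # BB x BB -> BB

#' Mendelian consistency of a trio genotype configuration
#'
#' Classifies offspring/sire/dam genotype triples at an autosomal biallelic
#' site as \code{"consistent"} (the offspring can be formed from one allele
#' of each parent), \code{"error"} (a Mendelian error), or
#' \code{"uninformative"} (any member missing). Vectorised over triples.
#'
#' @param gOff,gSire,gDam genotype codes in \code{{0, 1, 2, NA}} (alt-allele
#'   counts), equal length.
#' @return character vector over
#'   \code{c("consistent", "error", "uninformative")}.
#' @examples
#' mendelCheckTrio(1, 0, 0)   # "error": AA x AA cannot yield AB
#' mendelCheckTrio(1, 0, 2)   # "consistent": AA x BB must yield AB
#' @export
mendelCheckTrio <- function(gOff, gSire, gDam) {
  n <- length(gOff)
  if (length(gSire) != n || length(gDam) != n)
    stop("gOff, gSire and gDam must have equal length")
  g <- cbind(as.integer(gOff), as.integer(gSire), as.integer(gDam))
  if (any(!(g %in% c(0L, 1L, 2L, NA))))
    stop("genotype codes must be 0, 1, 2 or NA")
  out <- rep("uninformative", n)
  comp <- rowSums(is.na(g)) == 0L
  if (any(comp)) {
    ok <- .MENDEL_OK[g[comp, , drop = FALSE] + 1L]
    out[comp] <- ifelse(ok, "consistent", "error")
  }
  out
}

#' Expected fraction of trios informative for Mendelian errors
#'
#' Models the chance that a trio can reveal a Mendelian inconsistency at a
#' biallelic site of minor allele frequency \eqn{p} as the probability that
#' at least one of three independent Hardy-Weinberg genotypes is
#' heterozygous:
#' \deqn{f(p) = 1 - (1 - 2p(1-p))^3.}
#' \eqn{f} is 0 for monomorphic sites, increases monotonically on
#' \eqn{[0, 0.5]}, and attains its maximum \eqn{0.875} at \eqn{p = 0.5}.
#' Treating the three members as independent is an approximation: under
#' true Mendelian transmission the trio genotypes are correlated, and the
#' approximation is exact only at \eqn{p = 0.5}.
#'
#' @param p minor allele frequency, in \eqn{[0, 0.5]} (values up to 1 are
#'   accepted and folded implicitly by the symmetric formula).
#' @return expected informative fraction in \eqn{[0, 0.875]}.
#' @examples
#' expectedInformativeFraction(c(0, 0.25, 0.5))
#' @export
expectedInformativeFraction <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p must lie in [0, 1]")
  1 - (1 - 2 * p * (1 - p))^3
}

#' Scan a callset for Mendelian errors
#'
#' Classifies every (site, trio) pair with [mendelCheckTrio()] and
#' aggregates: per site, the number of complete trios (all three members
#' called), informative trios (complete trios with at least one
#' heterozygous member, plus any error configuration — so errors never
#' exceed the informative count), errors, the error rate (errors per
#' informative trio), and the model expectation
#' [expectedInformativeFraction()] at the site's MAF; per sample, total
#' errors over the trios in which the sample is the offspring.
#'
#' @param gm a [GenotypeCalls-class].
#' @param ped pedigree data.frame with columns \code{id}, \code{sire},
#'   \code{dam} (FAM-style files from [readFam()] work directly). Trios
#'   whose three members are not all present among the samples are skipped.
#' @return a [MendelReport-class].
#' @export
mendelScan <- function(gm, ped) {
  stopifnot(is(gm, "GenotypeCalls"), is.data.frame(ped))
  need <- c("id", "sire", "dam")
  if (!all(need %in% colnames(ped)))
    stop("pedigree must have columns id, sire, dam")
  m <- calls(gm)
  samples <- colnames(m)
  keep <- ped$id %in% samples & ped$sire %in% samples & ped$dam %in% samples &
    ped$id != ped$sire & ped$id != ped$dam & ped$sire != ped$dam
  trios <- ped[keep, , drop = FALSE]
  if (nrow(trios) == 0L)
    stop("no resolvable trios in the pedigree")
  oi <- match(trios$id, samples)
  si <- match(trios$sire, samples)
  di <- match(trios$dam, samples)
  gO <- m[, oi, drop = FALSE]
  gS <- m[, si, drop = FALSE]
  gD <- m[, di, drop = FALSE]
  complete <- !is.na(gO) & !is.na(gS) & !is.na(gD)
  err <- matrix(FALSE, nrow(m), nrow(trios))
  err[complete] <- !.MENDEL_OK[cbind(gO[complete] + 1L, gS[complete] + 1L,
                                     gD[complete] + 1L)]
  anyHet <- complete & (gO == 1L | gS == 1L | gD == 1L)
  informative <- complete & (anyHet | err)
  maf <- siteMAF(gm)
  si_ <- siteInfo(gm)
  nInf <- as.integer(rowSums(informative))
  nErr <- as.integer(rowSums(err))
  perSite <- data.frame(
    chrom = si_$chrom, pos = si_$pos, maf = maf,
    nComplete = as.integer(rowSums(complete)),
    nInformative = nInf,
    nErrors = nErr,
    errorRate = ifelse(nInf > 0L, nErr / nInf, NA_real_),
    expectedInformative = expectedInformativeFraction(
      ifelse(is.na(maf), 0, maf)),
    stringsAsFactors = FALSE)
  # aggregate over trios sharing an offspring (errors attributed to
  # the offspring)
  errBySample <- rowsum(colSums(err), trios$id)
  infBySample <- rowsum(colSums(informative), trios$id)
  trioBySample <- rowsum(rep(1L, nrow(trios)), trios$id)
  perSample <- data.frame(
    sample = rownames(errBySample),
    nTrios = as.integer(trioBySample[, 1L]),
    nErrors = as.integer(errBySample[, 1L]),
    errorRate = ifelse(infBySample[, 1L] > 0L,
                       errBySample[, 1L] / infBySample[, 1L], NA_real_),
    row.names = NULL, stringsAsFactors = FALSE)
  new("MendelReport", perSite = perSite, perSample = perSample,
      nTrios = nrow(trios))
}

#' @describeIn MendelReport-class per-site table.
#' @export
setMethod("perSite", "MendelReport", function(x) x@perSite)

#' @describeIn MendelReport-class per-sample (offspring) table.
#' @export
setMethod("perSample", "MendelReport", function(x) x@perSample)

#' @describeIn MendelReport-class display.
#' @param object a [MendelReport-class].
#' @export
setMethod("show", "MendelReport", function(object) {
  cat(sprintf(
    "MendelReport: %d trios x %d sites; mean site error rate %.4g\n",
    object@nTrios, nrow(object@perSite),
    mean(object@perSite$errorRate, na.rm = TRUE)))
})

#' Mendelian-error removal thresholds
#'
#' Applies the two removal rules used after a trio scan: sites whose error
#' rate strictly exceeds \code{siteRateThreshold} (default 0.005, so a site
#' at exactly the threshold is retained), and samples whose total error
#' count strictly exceeds \code{sampleMultipleOfMean} times the mean
#' per-sample error count (default an order of magnitude).
#'
#' @param report a [MendelReport-class].
#' @param siteRateThreshold per-informative-trio error-rate cutoff.
#' @param sampleMultipleOfMean multiple of the sample-mean error count.
#' @return list with \code{sites} (data.frame chrom/pos of removed sites),
#'   \code{samples} (character), and \code{thresholds}.
#' @seealso [suggestSiteThreshold()] for a data-driven site threshold.
#' @export
mendelFilter <- function(report, siteRateThreshold = 0.005,
                         sampleMultipleOfMean = 10) {
  stopifnot(is(report, "MendelReport"))
  s <- report@perSite
  bad <- !is.na(s$errorRate) & s$errorRate > siteRateThreshold
  p <- report@perSample
  meanErr <- mean(p$nErrors)
  badSample <- p$nErrors > sampleMultipleOfMean * meanErr
  list(sites = s[bad, c("chrom", "pos", "errorRate")],
       samples = p$sample[badSample],
       thresholds = list(siteRate = siteRateThreshold,
                         sampleMultipleOfMean = sampleMultipleOfMean,
                         sampleMeanErrors = meanErr))
}

#' Data-driven site error-rate threshold (advisory)
#'
#' Proposes a site error-rate cutoff as the inflection of the sorted
#' per-site error-rate curve: rates are sorted ascending, averaged in
#' \code{nBins} fixed-width bins along the rank axis, the bend is located at
#' the maximum discrete second difference, and the threshold is placed
#' midway between the bend bin and the next one (i.e. inside the gap
#' separating the clean mass from the outlier tail). Advisory only — the
#' conventional printed defaults remain the defaults of [mendelFilter()].
#'
#' @param report a [MendelReport-class].
#' @param nBins number of rank-axis bins, default 50.
#' @return proposed threshold, or \code{NA} if the curve is degenerate
#'   (fewer than 3 usable bins or constant rates).
#' @export
suggestSiteThreshold <- function(report, nBins = 50L) {
  stopifnot(is(report, "MendelReport"))
  r <- sort(report@perSite$errorRate[!is.na(report@perSite$errorRate)])
  if (length(r) < 3L || diff(range(r)) == 0) return(NA_real_)
  nBins <- min(nBins, length(r))
  bin <- cut(seq_along(r), breaks = nBins, labels = FALSE)
  means <- tapply(r, bin, mean)
  if (length(means) < 3L) return(NA_real_)
  d2 <- diff(diff(means))
  k <- which.max(d2) + 1L
  if (k >= length(means)) return(unname(means[k]))
  unname((means[k] + means[k + 1L]) / 2)
}
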