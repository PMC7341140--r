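#' Infer sample sex from X-chromosome read fractions
#'
#' For each sample, divides reads mapped to the X chromosome by total mapped
#' reads and calls the sample female when the fraction strictly exceeds the
#' threshold (default 3\%), male otherwise. Samples with zero mapped reads
#' get an undefined flag and an \code{NA} inference rather than an error.
#' When a pedigree with recorded sex is supplied, mismatches between
#' recorded and inferred sex are flagged.
#'
#' @param readCounts idxstats-style long data.frame with columns
#'   \code{sample}, \code{contig}, \code{mapped} (see [readIdxstats()]).
#' @param threshold X-read fraction above which a sample is called female.
#' @param ped optional data.frame with columns \code{id} and \code{sex}
#'   (\code{"M"}/\code{"F"}, or PLINK codes 1/2; anything else is treated
#'   as unknown).
#' @param xContig contig names counted as the X chromosome.
#' @return a [SexCheckReport-class].
#' @examples
#' rc <- data.frame(sample = rep("s1", 2), contig = c("chr1", "chrX"),
#'                  mapped = c(95, 5))
#' perSample(sexInfer(rc))
#' @export
sexInfer <- function(readCounts, threshold = 0.03, ped = NULL,
                     xContig = c("X", "chrX")) {
  stopifnot(is.data.frame(readCounts))
  need <- c("sample", "contig", "mapped")
  if (!all(need %in% colnames(readCounts)))
    stop("readCounts must have columns sample, contig, mapped")
  if (!any(readCounts$contig %in% xContig))
    stop("no X-labelled contig found (looked for: ",
         paste(xContig, collapse = ", "), ")")
  tot <- rowsum(as.numeric(readCounts$mapped), readCounts$sample)
  isX <- readCounts$contig %in% xContig
  xr <- rowsum(as.numeric(readCounts$mapped) * isX, readCounts$sample)
  samples <- rownames(tot)
  xFraction <- ifelse(tot[, 1] > 0, xr[, 1] / tot[, 1], NA_real_)
  inferred <- ifelse(is.na(xFraction), NA_character_,
                     ifelse(xFraction > threshold, "F", "M"))
  recorded <- rep(NA_character_, length(samples))
  if (!is.null(ped)) {
    stopifnot(all(c("id", "sex") %in% colnames(ped)))
    sx <- as.character(ped$sex[match(samples, ped$id)])
    sx[sx == "1"] <- "M"; sx[sx == "2"] <- "F"
    sx[!sx %in% c("M", "F")] <- NA_character_
    recorded <- sx
  }
  tab <- data.frame(
    sample = samples,
    xReads = xr[, 1], totalReads = tot[, 1],
    xFraction = xFraction,
    inferredSex = inferred,
    recordedSex = recorded,
    mismatch = !is.na(inferred) & !is.na(recorded) & inferred != recorded,
    undefined = is.na(xFraction),
    row.names = NULL, stringsAsFactors = FALSE)
  new("SexCheckReport", table = tab, threshold = threshold)
}

#' @describeIn SexCheckReport-class the per-sample table.
#' @param x a [SexCheckReport-class].
#' @export
setMethod("perSample", "SexCheckReport", function(x) x@table)

#' @describeIn SexCheckReport-class display.
#' @param object a [SexCheckReport-class].
#' @export
setMethod("show", "SexCheckReport", function(object) {
  t <- object@table
  cat(sprintf(
    "SexCheckReport (threshold %.3g): %d samples, %d F / %d M, %d mismatch, %d undefined\n",
    object@threshold, nrow(t),
    sum(t$inferredSex == "F", na.rm = TRUE),
    sum(t$inferredSex == "M", na.rm = TRUE),
    sum(t$mismatch), sum(t$undefined)))
})

#' Transition/transversion ratio
#'
#' Classifies biallelic substitutions into transitions (A<->G, C<->T) and
#' transversions (all other pairs) and returns their ratio. A callset with
#' no transversions has an undefined ratio: \code{NA} is returned with a
#' warning rather than \code{Inf}.
#'
#' @param ref,alt reference and alternate allele vectors (single bases), or
#'   a [GenotypeCalls-class] as the first argument.
#' @return the Ts/Tv ratio (expected around 2 genome-wide for mammalian
#'   callsets).
#' @examples
#' tstvRatio(c("A", "C", "A", "G"), c("G", "T", "C", "T"))  # 1
#' @export
tstvRatio <- function(ref, alt = NULL) {
  if (is(ref, "GenotypeCalls")) {
    si <- siteInfo(ref)
    alt <- si$alt
    ref <- si$ref
  }
  ref <- toupper(ref); alt <- toupper(alt)
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt
  if (!all(ok)) stop("ref/alt must be distinct single bases A/C/G/T")
  ts <- (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
        (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
  nTs <- sum(ts); nTv <- sum(!ts)
  if (nTv == 0L) {
    warning("no transversions: Ts/Tv undefined")
    return(NA_real_)
  }
  nTs / nTv
}

#' Genotype concordance between two callsets
#'
#' Matches sites on (chrom, pos). Sites with identical ref/alt are compared
#' directly; sites with swapped ref/alt have the second callset's codes
#' flipped (0 <-> 2) before comparison, except A/T and C/G sites, where a
#' swap is indistinguishable from a strand flip — those are excluded and
#' counted in \code{nAmbiguousExcluded}. Sites whose allele pairs match
#' neither way are excluded and counted in \code{nAlleleMismatch}.
#' Discordance is the fraction of differing calls among jointly non-missing
#' calls, reported overall, per sample and per site, together with the
#' number of sites at or below each discordance threshold on a grid.
#'
#' @param a,b [GenotypeCalls-class] objects sharing at least one sample id.
#' @param grid discordance thresholds for the site-count curve.
#' @return a [ConcordanceReport-class].
#' @export
concordance <- function(a, b, grid = seq(0, 0.2, by = 0.01)) {
  stopifnot(is(a, "GenotypeCalls"), is(b, "GenotypeCalls"))
  sa <- siteInfo(a); sb <- siteInfo(b)
  keyA <- paste(sa$chrom, sa$pos); keyB <- paste(sb$chrom, sb$pos)
  common <- intersect(keyA, keyB)
  if (length(common) == 0L)
    stop("no overlapping sites between the two callsets")
  samples <- intersect(colnames(calls(a)), colnames(calls(b)))
  if (length(samples) == 0L)
    stop("no overlapping samples between the two callsets")
  ia <- match(common, keyA); ib <- match(common, keyB)
  refA <- sa$ref[ia]; altA <- sa$alt[ia]
  refB <- sb$ref[ib]; altB <- sb$alt[ib]
  same <- refA == refB & altA == altB
  swapped <- refA == altB & altA == refB & !same
  ambiguous <- swapped & (paste0(refA, altA) %in% c("AT", "TA", "CG", "GC"))
  usable <- same | (swapped & !ambiguous)
  nMismatch <- sum(!same & !swapped)
  nAmbig <- sum(ambiguous)
  ia <- ia[usable]; ib <- ib[usable]
  flip <- swapped[usable]
  if (length(ia) == 0L)
    stop("no overlapping sites with compatible alleles")
  ma <- calls(a)[ia, samples, drop = FALSE]
  mb <- calls(b)[ib, samples, drop = FALSE]
  mb[flip, ] <- 2L - mb[flip, , drop = FALSE]
  joint <- !is.na(ma) & !is.na(mb)
  diffc <- joint & (ma != mb)
  overall <- if (sum(joint)) sum(diffc) / sum(joint) else NA_real_
  perSample <- data.frame(
    sample = samples,
    nCompared = as.integer(colSums(joint)),
    nDiscordant = as.integer(colSums(diffc)),
    discordance = ifelse(colSums(joint) > 0, colSums(diffc) / colSums(joint),
                         NA_real_),
    row.names = NULL, stringsAsFactors = FALSE)
  perSite <- data.frame(
    chrom = sa$chrom[ia], pos = sa$pos[ia],
    nCompared = as.integer(rowSums(joint)),
    nDiscordant = as.integer(rowSums(diffc)),
    discordance = ifelse(rowSums(joint) > 0, rowSums(diffc) / rowSums(joint),
                         NA_real_),
    row.names = NULL, stringsAsFactors = FALSE)
  curve <- data.frame(
    threshold = grid,
    nSites = vapply(grid, function(t)
      sum(perSite$discordance <= t, na.rm = TRUE), integer(1)))
  new("ConcordanceReport",
      overall = overall,
      nSitesCompared = length(ia),
      nAlleleMismatch = as.integer(nMismatch),
      nAmbiguousExcluded = as.integer(nAmbig),
      perSample = perSample, perSite = perSite, thresholdCurve = curve)
}

#' @describeIn ConcordanceReport-class per-sample discordance.
#' @export
setMethod("perSample", "ConcordanceReport", function(x) x@perSample)

#' @describeIn ConcordanceReport-class per-site discordance.
#' @export
setMethod("perSite", "ConcordanceReport", function(x) x@perSite)

#' @describeIn ConcordanceReport-class display.
#' @param object a [ConcordanceReport-class].
#' @export
setMethod("show", "ConcordanceReport", function(object) {
  cat(sprintf(
    "ConcordanceReport: %d sites, overall discordance %.4g (%d allele-mismatch, %d strand-ambiguous excluded)\n",
    object@nSitesCompared, object@overall, object@nAlleleMismatch,
    object@nAmbiguousExcluded))
})

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test for a biallelic site, conditioning on the observed
#' allele counts and enumerating the distribution of the heterozygote count
#' (Wigginton-style recurrence). The p-value sums the probabilities of all
#' heterozygote counts whose probability does not exceed that of the
#' observed count, so p is always in (0, 1] and equals 1 for monomorphic
#' sites.
#'
#' @param nHomRef,nHet,nHomAlt genotype counts (non-negative, at least one
#'   individual in total). Vectors are accepted and recycled to a common
#'   length.
#' @return p-value(s) in (0, 1].
#' @examples
#' hweExactTest(20, 10, 20)
#' hweExactTest(25, 0, 0)  # monomorphic: 1
#' @export
hweExactTest <- function(nHomRef, nHet, nHomAlt) {
  n <- max(length(nHomRef), length(nHet), length(nHomAlt))
  a <- rep_len(as.integer(nHomRef), n)
  b <- rep_len(as.integer(nHet), n)
  c_ <- rep_len(as.integer(nHomAlt), n)
  if (any(is.na(a + b + c_)) || any(c(a, b, c_) < 0))
    stop("genotype counts must be non-negative integers")
  if (any(a + b + c_ == 0L))
    stop("at least one individual is required")
  vapply(seq_len(n), function(i) .hwe1(a[i], b[i], c_[i]), numeric(1))
}

## single-site exact HWE p-value by heterozygote-count recurrence
.hwe1 <- function(a, b, c_) {
  n <- a + b + c_
  nRare <- min(2L * a + b, 2L * c_ + b)
  probs <- .hweHetDistribution(n, nRare)
  obs <- b  # heterozygote count; probs indexed by het = parity..nRare
  hets <- as.integer(names(probs))
  pObs <- probs[match(obs, hets)]
  if (is.na(pObs)) stop("observed het count incompatible with allele counts")
  # relative tolerance keeps exact ties (symmetric distributions) included
  # identically across floating-point routes
  min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

## distribution of the heterozygote count given n individuals and nRare
## copies of the rarer allele; named vector over feasible het counts
.hweHetDistribution <- function(n, nRare) {
  parity <- nRare %% 2L
  hets <- seq.int(parity, nRare, by = 2L)
  lp <- vapply(hets, function(h) {
    r <- (nRare - h) %/% 2L       # rare homozygotes
    d <- n - r - h                # common homozygotes
    lgamma(n + 1) - lgamma(r + 1) - lgamma(h + 1) - lgamma(d + 1) +
      h * log(2)
  }, numeric(1))
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  names(p) <- hets
  p
}

#' Sequential site filtering
#'
#' Applies the standard post-genotyping site filters in a fixed, documented
#' order, attributing each removed site to the first rule it fails so the
#' per-rule counts are reproducible:
#' \enumerate{
#'   \item \code{known} — site absent from the supplied list of previously
#'     identified variants (skipped when \code{knownSites} is NULL);
#'   \item \code{biallelic} — ref/alt not two distinct single bases;
#'   \item \code{minCalled} — fewer than \code{minCalledIndividuals}
#'     non-missing calls;
#'   \item \code{maf} — minor allele frequency strictly below
#'     \code{mafMin} (a site at exactly the threshold is retained);
#'   \item \code{callRate} — call rate strictly below \code{callRateMin};
#'   \item \code{hwe} — Hardy-Weinberg exact p strictly below
#'     \code{hwePMin}.
#' }
#'
#' @param gm a [GenotypeCalls-class].
#' @param knownSites NULL, or a data.frame with columns \code{chrom},
#'   \code{pos} (and optionally \code{ref}, \code{alt}, then matched too).
#' @param mafMin,callRateMin,hwePMin,minCalledIndividuals thresholds; the
#'   defaults are the conventional ddGBS values (0.005, 0.90, 1e-10, 2).
#' @param biallelicOnly apply the biallelic rule.
#' @return list with \code{gm} (the filtered [GenotypeCalls-class]) and
#'   \code{removed}, a named integer vector of per-rule removal counts.
#' @export
filterSites <- function(gm, knownSites = NULL, mafMin = 0.005,
                        callRateMin = 0.90, hwePMin = 1e-10,
                        minCalledIndividuals = 2L, biallelicOnly = TRUE) {
  stopifnot(is(gm, "GenotypeCalls"))
  si <- siteInfo(gm)
  nSites <- nrow(si)
  rules <- c("known", "biallelic", "minCalled", "maf", "callRate", "hwe")
  removed <- stats::setNames(integer(length(rules)), rules)
  alive <- rep(TRUE, nSites)

  fail <- function(idx) { # attribute to first failing rule
    idx & alive
  }
  if (!is.null(knownSites)) {
    stopifnot(all(c("chrom", "pos") %in% colnames(knownSites)))
    if (all(c("ref", "alt") %in% colnames(knownSites)))
      keys <- paste(knownSites$chrom, knownSites$pos, knownSites$ref,
                    knownSites$alt)
    else keys <- paste(knownSites$chrom, knownSites$pos)
    here <- if (all(c("ref", "alt") %in% colnames(knownSites)))
      paste(si$chrom, si$pos, si$ref, si$alt)
    else paste(si$chrom, si$pos)
    bad <- fail(!(here %in% keys))
    removed["known"] <- sum(bad); alive[bad] <- FALSE
  }
  if (biallelicOnly) {
    bases <- c("A", "C", "G", "T")
    bad <- fail(!(si$ref %in% bases & si$alt %in% bases & si$ref != si$alt))
    removed["biallelic"] <- sum(bad); alive[bad] <- FALSE
  }
  nCalled <- rowSums(!is.na(calls(gm)))
  bad <- fail(nCalled < minCalledIndividuals)
  removed["minCalled"] <- sum(bad); alive[bad] <- FALSE

  maf <- siteMAF(gm)
  bad <- fail(!is.na(maf) & maf < mafMin)
  removed["maf"] <- sum(bad); alive[bad] <- FALSE

  cr <- siteCallRate(gm)
  bad <- fail(cr < callRateMin)
  removed["callRate"] <- sum(bad); alive[bad] <- FALSE

  if (any(alive)) {
    gc_ <- genotypeCounts(gm)
    idx <- which(alive & nCalled >= 1L)  # HWE undefined with no calls
    p <- hweExactTest(gc_[idx, "nHomRef"], gc_[idx, "nHet"],
                      gc_[idx, "nHomAlt"])
    badIdx <- idx[p < hwePMin]
    removed["hwe"] <- length(badIdx); alive[badIdx] <- FALSE
  }
  list(gm = gm[alive, ], removed = removed)
}
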