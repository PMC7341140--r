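## run expr under a fixed seed without disturbing the caller's RNG stream
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## random DNA of given length and GC content, rejection-cleaned so that none
## of the motifs (plain ACGT strings) occurs anywhere
.cleanDNA <- function(len, motifs, gc = 0.5, maxIter = 100L) {
  if (len == 0L) return("")
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  x <- sample(names(prob), len, replace = TRUE, prob = prob)
  seqStr <- paste(x, collapse = "")
  for (iter in seq_len(maxIter)) {
    hits <- unlist(lapply(motifs, function(m)
      as.vector(gregexpr(m, seqStr, fixed = TRUE)[[1]])))
    hits <- hits[hits > 0]
    if (length(hits) == 0L) return(seqStr)
    for (h in hits) # resample one base inside each occurrence
      substr(seqStr, h, h) <- sample(setdiff(names(prob),
                                             substr(seqStr, h, h)), 1L)
  }
  stop("could not generate motif-free background; lower gc or shorten motifs")
}

.motifsOf <- function(enzymes) {
  unique(unlist(lapply(enzymes, function(e) {
    rec <- recognitionSite(e)
    c(rec, as.character(reverseComplement(DNAString(rec))))
  })))
}

#' Generate a genome with planted double-digest fragments
#'
#' Builds a synthetic chromosome consisting of motif-free background
#' interleaved with planted cassettes, each cassette carrying one
#' primary-enzyme site and one secondary-enzyme site positioned so the
#' fragment between their cut points has exactly the requested insert
#' length. Cassette orientation alternates (primary-then-secondary,
#' secondary-then-primary), which makes every fragment \emph{between}
#' cassettes a PP or SS fragment — so the planted fragments are exactly the
#' PS fragments of the digest, and with spacers of at least
#' \code{minSpacer} bp no unplanted fragment can fall into a size window
#' narrower than that. Background and fillers are rejection-sampled free of
#' all involved recognition sites (and their reverse complements), and the
#' assembled genome is verified: every recognition site in it is a planted
#' one (junction-spanning accidental sites are repaired by point mutation).
#'
#' This construction makes planted capture fractions exact by design; it
#' does not emulate the repeat structure, GC heterogeneity or assembly gaps
#' of a real genome.
#'
#' @param genomeBp total genome length in bp.
#' @param inserts integer vector of planted PS insert lengths (may be
#'   empty: the result then contains no recognition site at all).
#' @param primary primary [RestrictionEnzyme-class] (default PstI).
#' @param secondary secondary [RestrictionEnzyme-class], or a list of
#'   enzymes parallel to \code{inserts} for mixed-cassette genomes.
#' @param gc background GC content.
#' @param avoid additional [RestrictionEnzyme-class] objects whose sites
#'   must not occur in the background (useful when the genome will be
#'   digested with several candidate enzymes).
#' @param minSpacer minimum background run between cassettes; packing that
#'   cannot honour it is an error.
#' @param seed integer seed; identical arguments and seed give an
#'   identical genome.
#' @return list with \code{genome} (a one-sequence \code{DNAStringSet}
#'   named \code{"chr1"}), \code{cuts} (data.frame \code{pos} (0-based
#'   between-base), \code{enzyme}) and \code{fragments} (data.frame of the
#'   planted PS fragments: \code{start}, \code{end} 0-based half-open,
#'   \code{length}, \code{secondary}).
#' @examples
#' gx <- makeGenome(20000, inserts = c(200, 150), seed = 7)
#' gx$fragments
#' @export
makeGenome <- function(genomeBp, inserts = integer(),
                       primary = enzymeCatalog()$PstI,
                       secondary = enzymeCatalog()$NlaIII,
                       gc = 0.5, avoid = list(), minSpacer = 500L,
                       seed = 1L) {
  inserts <- as.integer(inserts)
  genomeBp <- as.integer(genomeBp)
  n <- length(inserts)
  secondaries <- if (is(secondary, "RestrictionEnzyme"))
    rep(list(secondary), n) else secondary
  if (n > 0L && length(secondaries) != n)
    stop("'secondary' must be one enzyme or a list parallel to 'inserts'")
  secEnz <- if (is(secondary, "RestrictionEnzyme")) list(secondary)
            else secondaries
  motifs <- .motifsOf(c(list(primary), secEnz, avoid))
  .withSeed(seed, {
    cassettes <- vector("list", n)
    meta <- vector("list", n)
    for (i in seq_len(n)) {
      S <- secondaries[[i]]
      recP <- recognitionSite(primary); recS <- recognitionSite(S)
      mP <- nchar(recP); mS <- nchar(recS)
      cP <- cutOffset(primary); cS <- cutOffset(S)
      forward <- i %% 2L == 1L
      fLen <- if (forward) inserts[i] - mP - cS + cP
              else         inserts[i] - mS - cP + cS
      if (fLen < 0L)
        stop("infeasible packing: insert ", inserts[i],
             " bp too short for the two recognition sites")
      filler <- .cleanDNA(fLen, motifs, gc)
      if (forward) {
        cassettes[[i]] <- paste0(recP, filler, recS)
        meta[[i]] <- list(cutP = cP, cutS = mP + fLen + cS,
                          siteP = 0L, siteS = mP + fLen, enzS = S@name)
      } else {
        cassettes[[i]] <- paste0(recS, filler, recP)
        meta[[i]] <- list(cutP = mS + fLen + cP, cutS = cS,
                          siteP = mS + fLen, siteS = 0L, enzS = S@name)
      }
    }
    cassLen <- vapply(cassettes, nchar, integer(1))
    spare <- genomeBp - sum(cassLen)
    spacerLen <- rep(spare %/% (n + 1L), n + 1L)
    spacerLen[1L] <- spacerLen[1L] + spare %% (n + 1L)
    if (any(spacerLen < minSpacer))
      stop("infeasible packing: planted cassettes leave spacers shorter ",
           "than minSpacer (", minSpacer, " bp) in a ", genomeBp,
           " bp genome")
    parts <- character(2L * n + 1L)
    offsets <- integer(n)
    pos <- 0L
    for (i in seq_len(n)) {
      parts[2L * i - 1L] <- .cleanDNA(spacerLen[i], motifs, gc)
      pos <- pos + spacerLen[i]
      offsets[i] <- pos
      parts[2L * i] <- cassettes[[i]]
      pos <- pos + cassLen[i]
    }
    parts[2L * n + 1L] <- .cleanDNA(spacerLen[n + 1L], motifs, gc)
    genomeStr <- paste(parts, collapse = "")
    stopifnot(nchar(genomeStr) == genomeBp)

    # expected 0-based site starts per enzyme
    expected <- list()
    for (i in seq_len(n)) {
      expected[[primary@name]] <- c(expected[[primary@name]],
                                    offsets[i] + meta[[i]]$siteP)
      nm <- meta[[i]]$enzS
      expected[[nm]] <- c(expected[[nm]], offsets[i] + meta[[i]]$siteS)
    }
    allEnz <- c(list(primary), secEnz[!duplicated(
      vapply(secEnz, enzymeName, character(1)))])
    genomeStr <- .repairUnplanted(genomeStr, allEnz, expected, motifs)

    cuts <- data.frame(pos = integer(), enzyme = character())
    frags <- data.frame(start = integer(), end = integer(),
                        length = integer(), secondary = character())
    if (n > 0L) {
      cuts <- data.frame(
        pos = c(offsets + vapply(meta, `[[`, integer(1), "cutP"),
                offsets + vapply(meta, `[[`, integer(1), "cutS")),
        enzyme = c(rep(primary@name, n),
                   vapply(meta, `[[`, character(1), "enzS")),
        stringsAsFactors = FALSE)
      cuts <- cuts[order(cuts$pos), ]
      rownames(cuts) <- NULL
      cutP <- offsets + vapply(meta, `[[`, integer(1), "cutP")
      cutS <- offsets + vapply(meta, `[[`, integer(1), "cutS")
      frags <- data.frame(start = pmin(cutP, cutS), end = pmax(cutP, cutS),
                          length = as.integer(inserts),
                          secondary = vapply(meta, `[[`, character(1),
                                             "enzS"),
                          stringsAsFactors = FALSE)
    }
    genome <- DNAStringSet(genomeStr)
    names(genome) <- "chr1"
    list(genome = genome, cuts = cuts, fragments = frags)
  })
}

## mutate away any recognition-site occurrence that is not a planted one
## (these can only arise spanning part junctions)
.repairUnplanted <- function(genomeStr, enzymes, expected, motifs,
                             maxIter = 100L) {
  planted <- lapply(expected, sort)
  protect <- unlist(lapply(names(planted), function(nm) {
    e <- Filter(function(z) enzymeName(z) == nm, enzymes)[[1]]
    unlist(lapply(planted[[nm]],
                  function(s) seq.int(s + 1L, s + nchar(recognitionSite(e)))))
  }))
  subject <- DNAString(genomeStr)
  for (iter in seq_len(maxIter)) {
    extra <- integer()
    for (e in enzymes) {
      hits <- scanRecognitionSites(subject, e)
      unexp <- setdiff(as.integer(hits), planted[[enzymeName(e)]])
      if (length(unexp))
        extra <- c(extra, unlist(lapply(unexp, function(s)
          seq.int(s + 1L, s + nchar(recognitionSite(e))))))
    }
    if (length(extra) == 0L)
      return(as.character(subject))
    target <- setdiff(extra, protect)
    if (length(target) == 0L)
      stop("planted sites collide; choose longer spacers")
    i <- target[1L]
    cur <- substr(genomeStr, i, i)
    substr(genomeStr, i, i) <- setdiff(c("A", "C", "G", "T"), cur)[
      sample.int(3L, 1L)]
    subject <- DNAString(genomeStr)
  }
  stop("could not repair junction-spanning recognition sites")
}

#' Simulate in-line barcoded GBS reads with known origin
#'
#' Emits single-end reads of layout \code{[barcode][residual][insert
#' prefix]} drawn from the planted fragments of a [makeGenome()] genome,
#' with a truth table recording each read's sample of origin. Exactly
#' \code{barcodeMismatches} substitutions can be planted into every read's
#' barcode (0 leaves barcodes intact; 2 places every read beyond the usual
#' demultiplexing tolerance). Base qualities are constant Q40.
#'
#' @param genome a \code{DNAStringSet} or the list returned by
#'   [makeGenome()] (its truth fragments are then used).
#' @param table a [BarcodeTable-class].
#' @param fragments data.frame of insert intervals (\code{start},
#'   \code{end}, 0-based half-open); defaults to the genome's planted
#'   fragments.
#' @param readsPerSample reads to emit per sample.
#' @param readLength read length in bp (reads are truncated to this).
#' @param barcodeMismatches substitutions planted in each barcode.
#' @param seed integer seed.
#' @return list with \code{reads} (\code{QualityScaledDNAStringSet}) and
#'   \code{truth} (data.frame \code{read}, \code{sample}).
#' @export
simulateGbsReads <- function(genome, table, fragments = NULL,
                             readsPerSample = 20L, readLength = 100L,
                             barcodeMismatches = 0L, seed = 1L) {
  stopifnot(is(table, "BarcodeTable"))
  if (is.list(genome) && !is(genome, "DNAStringSet")) {
    if (is.null(fragments)) fragments <- genome$fragments
    genome <- genome$genome
  }
  if (is.null(fragments) || nrow(fragments) == 0L)
    stop("no fragments to sequence: supply a genome with planted fragments")
  seqStr <- as.character(genome[[1]])
  res <- table@residual
  .withSeed(seed, {
    out <- list(); truth <- list(); k <- 0L
    for (j in seq_along(table@sampleId)) {
      bc <- table@barcode[j]
      for (r in seq_len(readsPerSample)) {
        k <- k + 1L
        f <- fragments[sample.int(nrow(fragments), 1L), ]
        insert <- substr(seqStr, f$start + 1L, f$end)
        bcRead <- bc
        if (barcodeMismatches > 0L) {
          posns <- sample.int(nchar(bc), min(barcodeMismatches, nchar(bc)))
          for (p in posns)
            substr(bcRead, p, p) <- sample(
              setdiff(c("A", "C", "G", "T"), substr(bc, p, p)), 1L)
        }
        readSeq <- substr(paste0(bcRead, res, insert), 1L, readLength)
        out[[k]] <- readSeq
        truth[[k]] <- table@sampleId[j]
      }
    }
    seqs <- DNAStringSet(unlist(out))
    names(seqs) <- sprintf("read%05d", seq_along(seqs))
    quals <- PhredQuality(vapply(width(seqs), function(w)
      strrep("I", w), character(1)))
    list(reads = QualityScaledDNAStringSet(seqs, quals),
         truth = data.frame(read = names(seqs),
                            sample = unlist(truth),
                            stringsAsFactors = FALSE))
  })
}

#' Simulate trio genotypes with planted Mendelian errors
#'
#' Draws, for each of \code{nTrios} independent trios and \code{nSites}
#' biallelic sites, parental genotypes from Hardy-Weinberg proportions at a
#' per-site minor allele frequency sampled uniformly from \code{mafRange},
#' and offspring genotypes by transmitting one allele per parent. Errors
#' are then planted among \emph{informative} trio-sites (at least one
#' member heterozygous) at rate \code{errorRate}: the offspring is set to a
#' genotype inconsistent with its parents, except for het x het parent
#' pairs (which admit any offspring), where the sire is set to hom-ref and
#' the offspring to hom-alt. Every planted perturbation is therefore a
#' guaranteed Mendelian error, and the truth table lists them all.
#'
#' @param nTrios,nSites dimensions.
#' @param mafRange range of the uniform per-site MAF distribution.
#' @param errorRate per-informative-trio-site planting rate.
#' @param seed integer seed.
#' @return list with \code{gm} (a [GenotypeCalls-class] over all
#'   \code{3 * nTrios} individuals), \code{ped} (data.frame \code{id},
#'   \code{sire}, \code{dam}, \code{sex}), \code{maf} (true per-site MAF)
#'   and \code{errors} (data.frame \code{site}, \code{trio}).
#' @export
simulateTrioGenotypes <- function(nTrios = 500L, nSites = 2000L,
                                  mafRange = c(0.05, 0.5), errorRate = 0,
                                  seed = 1L) {
  .withSeed(seed, {
    maf <- stats::runif(nSites, mafRange[1], mafRange[2])
    draw <- function() matrix(stats::rbinom(nSites * nTrios, 2L, maf),
                              nSites, nTrios)
    gS <- draw(); gD <- draw()
    gamete <- function(g) (g == 2L) +
      (g == 1L) * matrix(stats::rbinom(length(g), 1L, 0.5), nrow(g))
    gO <- gamete(gS) + gamete(gD)
    informative <- gO == 1L | gS == 1L | gD == 1L
    errors <- data.frame(site = integer(), trio = integer())
    if (errorRate > 0) {
      plant <- informative &
        matrix(stats::runif(nSites * nTrios) < errorRate, nSites)
      idx <- which(plant, arr.ind = TRUE)
      for (r in seq_len(nrow(idx))) {
        i <- idx[r, 1L]; j <- idx[r, 2L]
        s <- gS[i, j]; d <- gD[i, j]
        if (s == 1L && d == 1L) {
          gS[i, j] <- 0L; gO[i, j] <- 2L
        } else {
          bad <- which(!.MENDEL_OK[, s + 1L, d + 1L]) - 1L
          gO[i, j] <- if (length(bad) == 1L) bad else
            bad[sample.int(length(bad), 1L)]
        }
      }
      errors <- data.frame(site = idx[, 1L], trio = idx[, 2L])
    }
    off <- sprintf("O%04d", seq_len(nTrios))
    sire <- sprintf("S%04d", seq_len(nTrios))
    dam <- sprintf("D%04d", seq_len(nTrios))
    m <- cbind(gO, gS, gD)
    colnames(m) <- c(off, sire, dam)
    refAlt <- t(vapply(seq_len(nSites), function(i)
      sample(c("A", "C", "G", "T"), 2L), character(2)))
    gm <- genotypeCalls(m, chrom = rep("1", nSites),
                        pos = 1000L * seq_len(nSites),
                        ref = refAlt[, 1L], alt = refAlt[, 2L])
    ped <- data.frame(id = off, sire = sire, dam = dam,
                      sex = sample(c("M", "F"), nTrios, replace = TRUE),
                      stringsAsFactors = FALSE)
    list(gm = gm, ped = ped, maf = maf, errors = errors)
  })
}

#' Simulate per-chromosome read-count tables
#'
#' Emulates idxstats-style read counts for a set of samples with known sex:
#' each sample's X-read fraction is drawn from a normal distribution whose
#' mean depends on sex (defaults straddle the conventional 3\% decision
#' threshold), and the remaining reads are spread evenly over the
#' autosomes.
#'
#' @param sex named character vector of true sexes (\code{"M"}/\code{"F"});
#'   names are the sample ids.
#' @param xFractionF,xFractionM mean X-read fraction per sex.
#' @param sdFraction standard deviation of the per-sample fraction.
#' @param totalReads total mapped reads per sample (recycled; a 0 entry
#'   produces an all-zero table for that sample).
#' @param nAutosomes number of autosomal contigs (\code{chr1..chrN}).
#' @param seed integer seed.
#' @return long data.frame with columns \code{sample}, \code{contig},
#'   \code{length}, \code{mapped}, \code{unmapped}.
#' @export
simulateReadcountTables <- function(sex, xFractionF = 0.05,
                                    xFractionM = 0.01, sdFraction = 0.002,
                                    totalReads = 1e6, nAutosomes = 20L,
                                    seed = 1L) {
  stopifnot(!is.null(names(sex)), all(sex %in% c("M", "F")))
  totalReads <- rep_len(totalReads, length(sex))
  contigs <- c(paste0("chr", seq_len(nAutosomes)), "chrX")
  .withSeed(seed, {
    rows <- lapply(seq_along(sex), function(i) {
      mu <- if (sex[i] == "F") xFractionF else xFractionM
      f <- min(max(stats::rnorm(1L, mu, sdFraction), 0), 1)
      xReads <- round(totalReads[i] * f)
      auto <- totalReads[i] - xReads
      per <- c(rep(floor(auto / nAutosomes), nAutosomes), xReads)
      per[1L] <- per[1L] + auto - floor(auto / nAutosomes) * nAutosomes
      data.frame(sample = names(sex)[i], contig = contigs,
                 length = c(rep(100e6, nAutosomes), 80e6),
                 mapped = per, unmapped = 0,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
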