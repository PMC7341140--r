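test_that("catalog entries satisfy the palindromic overhang relation", {
  cat <- enzymeCatalog()
  expect_named(cat, c("PstI", "AluI", "BfaI", "DpnI", "HaeIII", "MluCI",
                      "MspI", "NlaIII"))
  for (e in cat) {
    expect_true(isPalindromicRecognition(recognitionSite(e)))
    expect_identical(overhangLength(e),
                     abs(2L * cutOffset(e) - nchar(recognitionSite(e))))
  }
  # the three anchor enzymes
  expect_identical(cutOffset(cat$PstI), 5L)
  expect_identical(overhangLength(cat$PstI), 4L)
  expect_identical(cutOffset(cat$NlaIII), 4L)
  expect_identical(overhangLength(cat$NlaIII), 4L)
  expect_identical(cutOffset(cat$MluCI), 0L)
  expect_identical(overhangLength(cat$MluCI), 4L)
})

test_that("invalid enzymes are rejected", {
  expect_error(restrictionEnzyme("bad", "", 0), "recognition")
  expect_error(restrictionEnzyme("bad", "CTXCAG", 2), "IUPAC")
  expect_error(restrictionEnzyme("bad", "CTGCAG", 9), "cutOffset")
})

test_that("site scanning matches the worked micro-examples", {
  cat <- enzymeCatalog()
  expect_identical(scanRecognitionSites("AACTGCAGG", cat$PstI), 2L)
  expect_identical(scanRecognitionSites("ACGTACGT", cat$PstI), integer())
  expect_identical(scanRecognitionSites("CATGCATG", cat$NlaIII), c(0L, 4L))
})

test_that("overlapping occurrences are all reported", {
  e <- restrictionEnzyme("pal", "ACGT", 2)   # palindromic 4-cutter
  s <- "ACGTACGTACGT"
  expect_identical(scanRecognitionSites(s, e), oracleScan(s, "ACGT"))
  # genuinely overlapping motif occurrences
  e2 <- restrictionEnzyme("NlaIII", "CATG", 4)
  expect_identical(scanRecognitionSites("CATGCATGCATG", e2), c(0L, 4L, 8L))
})

test_that("sites never match across assembly-gap Ns", {
  pst <- enzymeCatalog()$PstI
  expect_identical(scanRecognitionSites("AACTGNAGG", pst), integer())
  expect_identical(scanRecognitionSites("NNCTGCAGNN", pst), 2L)
})

test_that("IUPAC ambiguity codes in the recognition site are honoured", {
  e <- restrictionEnzyme("amb", "GRCGYC", 3)  # R={A,G}, Y={C,T}
  s <- "TTGACGTCTTGGCGCCTT"
  expect_identical(scanRecognitionSites(s, e), oracleScan(s, "GRCGYC"))
  expect_length(scanRecognitionSites(s, e), 2L)
})

test_that("non-palindromic enzymes are scanned on both strands", {
  # BspQI-like: GCTCTTC, cuts downstream; use a made-up offset inside site
  e <- restrictionEnzyme("nonpal", "GCTCTTC", 2, overhangLen = 3)
  expect_false(isPalindromicRecognition("GCTCTTC"))
  s <- paste0("AAA", "GCTCTTC", "TTTT", "GAAGAGC", "AAA")  # + then - site
  hits <- scanRecognitionSites(s, e)
  expect_identical(as.integer(hits), c(3L, 14L))
  expect_identical(attr(hits, "strand"), c("+", "-"))
  # + strand cut at 3+2; - strand cut mirrored: 14 + (7 - 2)
  expect_identical(cutPositions(hits, e, nchar(s)), c(5L, 19L))
})

test_that("cut coordinates are in-range, deduplicated and sorted", {
  cat <- enzymeCatalog()
  expect_identical(cutPositions(2L, cat$PstI, 9L), 7L)
  expect_identical(cutPositions(integer(), cat$PstI, 10L), integer())
  # NlaIII cut of the site at 4 falls at 8 == sequence end: dropped
  expect_identical(cutPositions(c(0L, 4L), cat$NlaIII, 8L), 4L)
  # MluCI cuts at the site start: a site at 0 yields no internal cut
  expect_identical(cutPositions(c(0L, 6L), cat$MluCI, 12L), 6L)
})
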