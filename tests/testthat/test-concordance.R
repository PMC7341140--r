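mkGm <- function(m, chrom = "1", pos = NULL, ref = "A", alt = "G",
                 samples = NULL) {
  n <- nrow(m)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(m)))
  genotypeCalls(m, chrom = rep_len(chrom, n), pos = pos,
                ref = rep_len(ref, n), alt = rep_len(alt, n),
                samples = samples)
}

test_that("a callset is fully concordant with itself", {
  set.seed(71)
  m <- matrix(sample(c(0L, 1L, 2L, NA), 200, replace = TRUE), 20, 10)
  gm <- mkGm(m)
  cr <- concordance(gm, gm)
  expect_identical(cr@overall, 0)
  expect_true(all(perSample(cr)$discordance == 0))
})

test_that("one differing call among ten joint calls gives 0.1", {
  m <- matrix(0L, 1, 10)
  m2 <- m; m2[1, 1] <- 1L
  cr <- concordance(mkGm(m), mkGm(m2))
  expect_identical(cr@overall, 0.1)
  expect_identical(perSite(cr)$discordance, 0.1)
})

test_that("swapped ref/alt sites are harmonised by flipping calls", {
  m <- matrix(c(0L, 1L, 2L, 0L), 2, 2)
  a <- mkGm(m, ref = c("A", "C"), alt = c("G", "T"))
  b <- mkGm(2L - m, ref = c("G", "T"), alt = c("A", "C"))  # swapped + flipped
  cr <- concordance(a, b)
  expect_identical(cr@overall, 0)
  expect_identical(cr@nSitesCompared, 2L)
})

test_that("strand-ambiguous swaps and allele mismatches are excluded", {
  m <- matrix(1L, 3, 4)
  a <- mkGm(m, ref = c("A", "A", "C"), alt = c("G", "T", "G"))
  # site 2 is A/T swapped (ambiguous), site 3 has different alleles
  b <- mkGm(m, ref = c("A", "T", "C"), alt = c("G", "A", "A"))
  cr <- concordance(a, b)
  expect_identical(cr@nSitesCompared, 1L)
  expect_identical(cr@nAmbiguousExcluded, 1L)
  expect_identical(cr@nAlleleMismatch, 1L)
})

test_that("missing calls drop out of both numerator and denominator", {
  a <- mkGm(matrix(c(0L, 1L, NA, 2L), 1, 4))
  b <- mkGm(matrix(c(0L, NA, 1L, 0L), 1, 4))
  cr <- concordance(a, b)
  # joint non-missing pairs: s1 (0,0) and s4 (2,0): one differs
  expect_identical(cr@overall, 0.5)
  expect_identical(sum(perSample(cr)$nCompared), 2L)
})

test_that("overall discordance is symmetric in its arguments", {
  set.seed(72)
  m1 <- matrix(sample(c(0L, 1L, 2L, NA), 300, replace = TRUE,
                      prob = c(.4, .3, .2, .1)), 30, 10)
  m2 <- m1
  flip <- sample(length(m2), 40)
  m2[flip] <- sample(c(0L, 1L, 2L), 40, replace = TRUE)
  a <- mkGm(m1); b <- mkGm(m2)
  expect_identical(concordance(a, b)@overall, concordance(b, a)@overall)
})

test_that("the threshold curve counts sites passing each grid point", {
  m <- matrix(0L, 2, 10)
  m2 <- m; m2[1, 1:5] <- 1L           # site 1 at 50% discordance
  cr <- concordance(mkGm(m), mkGm(m2), grid = c(0, 0.25, 0.5, 1))
  expect_identical(cr@thresholdCurve$nSites, c(1L, 1L, 2L, 2L))
})

test_that("disjoint callsets are an error", {
  a <- mkGm(matrix(0L, 2, 3))
  b <- mkGm(matrix(0L, 2, 3), pos = c(9999L, 8888L))
  expect_error(concordance(a, b), "overlapping sites")
  d <- mkGm(matrix(0L, 2, 3), samples = c("x", "y", "z"))
  expect_error(concordance(a, d), "overlapping samples")
})
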