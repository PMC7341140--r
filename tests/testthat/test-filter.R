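# 10-site fixture: site 2 absent from the known list, site 5 at MAF 0.001,
# site 8 at 50% call rate; everything else passes every rule
makeFilterFixture <- function() {
  nSamples <- 1000L
  m <- matrix(0L, 10, nSamples)
  # 25-sample cycle at exact HWE proportions for p = 0.2 (16/8/1)
  hweCycle <- c(rep(0L, 16), rep(1L, 8), 2L)
  for (i in 1:10) m[i, ] <- rep(hweCycle, length.out = nSamples)
  m[5, ] <- 0L; m[5, 1:2] <- 1L                      # MAF = 0.001
  m[8, seq(1, nSamples, by = 2)] <- NA               # call rate 0.5
  gm <- genotypeCalls(m, chrom = rep("1", 10), pos = 1:10 * 50L,
                      ref = rep("A", 10), alt = rep("G", 10))
  known <- data.frame(chrom = "1", pos = setdiff(1:10, 2L) * 50L)
  list(gm = gm, known = known)
}

test_that("per-rule removal counts attribute each site to its first failure", {
  fx <- makeFilterFixture()
  out <- filterSites(fx$gm, knownSites = fx$known)
  expect_identical(out$removed,
                   c(known = 1L, biallelic = 0L, minCalled = 0L,
                     maf = 1L, callRate = 1L, hwe = 0L))
  expect_identical(nrow(siteInfo(out$gm)), 7L)
  # removal counts always sum to input - output
  expect_identical(sum(out$removed),
                   nrow(siteInfo(fx$gm)) - nrow(siteInfo(out$gm)))
})

test_that("a fully passing callset comes back unchanged", {
  fx <- makeFilterFixture()
  m <- calls(fx$gm)[c(1, 3, 4), ]
  gm <- genotypeCalls(m, chrom = rep("1", 3), pos = c(1L, 2L, 3L),
                      ref = rep("A", 3), alt = rep("G", 3))
  out <- filterSites(gm)
  expect_identical(sum(out$removed), 0L)
  expect_identical(calls(out$gm), calls(gm))
})

test_that("boundary sites are retained under strict inequalities", {
  # MAF exactly 0.005 (5 alt alleles in 500 diploids) must survive
  m <- matrix(0L, 2, 500)
  m[1, 1:5] <- 1L            # p = 5/1000 = 0.005
  m[2, 1:4] <- 1L            # p = 0.004 < 0.005: removed
  gm <- genotypeCalls(m, chrom = c("1", "1"), pos = c(10L, 20L),
                      ref = c("A", "C"), alt = c("G", "T"))
  out <- filterSites(gm)
  expect_identical(out$removed[["maf"]], 1L)
  expect_identical(siteInfo(out$gm)$pos, 10L)
  # call rate exactly at the threshold survives
  m2 <- matrix(rep(c(rep(0L, 16), rep(1L, 8), 2L), 4), 1, 100)
  m2[1, 1:10] <- NA          # call rate exactly 0.90
  gm2 <- genotypeCalls(m2, chrom = "1", pos = 5L, ref = "A", alt = "G")
  expect_identical(sum(filterSites(gm2)$removed), 0L)
})

test_that("non-SNP and under-called sites fall to their own rules", {
  m <- matrix(c(0L, 1L, rep(NA, 10)), 3, 4)
  m[1, ] <- c(0L, 1L, 0L, 1L)
  m[2, ] <- c(0L, 1L, 0L, 0L)
  m[3, ] <- c(0L, NA, NA, NA)          # one call < minCalled = 2
  gm <- genotypeCalls(m, chrom = rep("1", 3), pos = c(1L, 2L, 3L),
                      ref = c("A", "AT", "G"), alt = c("G", "A", "C"))
  out <- filterSites(gm, mafMin = 0, callRateMin = 0)
  expect_identical(out$removed[["biallelic"]], 1L)
  expect_identical(out$removed[["minCalled"]], 1L)
})

test_that("gross HWE violations are removed at p < 1e-10", {
  m <- matrix(1L, 2, 200)              # 200 hets, zero homozygotes
  m[2, ] <- rep(c(0L, 1L, 0L, 0L), 50) # well-behaved site
  gm <- genotypeCalls(m, chrom = c("1", "1"), pos = c(1L, 2L),
                      ref = c("A", "C"), alt = c("G", "T"))
  out <- filterSites(gm, mafMin = 0, callRateMin = 0)
  expect_identical(out$removed[["hwe"]], 1L)
  expect_identical(siteInfo(out$gm)$pos, 2L)
})
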