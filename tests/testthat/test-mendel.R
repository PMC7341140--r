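test_that("trio consistency matches gamete enumeration on all 27 configurations", {
  cfg <- expand.grid(off = 0:2, sire = 0:2, dam = 0:2)
  got <- mendelCheckTrio(cfg$off, cfg$sire, cfg$dam)
  exp <- mapply(oracleMendel, cfg$off, cfg$sire, cfg$dam)
  expect_identical(got, unname(exp))
  # anchor cases
  expect_identical(mendelCheckTrio(1, 0, 0), "error")
  expect_identical(mendelCheckTrio(1, 0, 2), "consistent")
  expect_identical(mendelCheckTrio(0, 0, 2), "error")
})

test_that("missing members make a trio uninformative; bad codes error", {
  expect_identical(mendelCheckTrio(NA, 0, 0), "uninformative")
  expect_identical(mendelCheckTrio(1, NA, 2), "uninformative")
  expect_identical(mendelCheckTrio(1, 1, NA), "uninformative")
  expect_error(mendelCheckTrio(3, 0, 0), "codes")
  expect_error(mendelCheckTrio(c(1, 1), 0, 0), "equal length")
})

test_that("the informative-fraction model has the right endpoints and shape", {
  expect_identical(expectedInformativeFraction(0), 0)
  expect_equal(expectedInformativeFraction(0.5), 0.875)
  p <- seq(0, 0.5, by = 0.01)
  f <- expectedInformativeFraction(p)
  expect_true(all(diff(f) > 0))           # strictly increasing on [0, 0.5]
  expect_true(all(f >= 0 & f <= 0.875))
  expect_error(expectedInformativeFraction(-0.1), "\\[0, 1\\]")
  expect_error(expectedInformativeFraction(1.2), "\\[0, 1\\]")
})

test_that("error-free inheritance scans clean", {
  st <- simulateTrioGenotypes(nTrios = 80, nSites = 300, errorRate = 0,
                              seed = 51)
  rep <- mendelScan(st$gm, st$ped)
  expect_identical(sum(perSite(rep)$nErrors), 0L)
  expect_identical(sum(perSample(rep)$nErrors), 0L)
  expect_identical(rep@nTrios, 80L)
})

test_that("a planted error rate of 0.01 is recovered within 3 binomial SEs", {
  st <- simulateTrioGenotypes(nTrios = 500, nSites = 2000, errorRate = 0.01,
                              seed = 1)
  rep <- mendelScan(st$gm, st$ped)
  ps <- perSite(rep)
  nInf <- sum(ps$nInformative)
  rate <- sum(ps$nErrors) / nInf
  se <- sqrt(0.01 * 0.99 / nInf)
  expect_lt(abs(rate - 0.01), 3 * se)
  # every planted perturbation is detected, nothing else is flagged
  expect_identical(sum(ps$nErrors), nrow(st$errors))
})

test_that("the scan recovers the planted truth exactly at smaller scales", {
  for (seed in c(2, 3, 4)) {
    st <- simulateTrioGenotypes(nTrios = 100, nSites = 400,
                                errorRate = 0.02, seed = seed)
    ps <- perSite(mendelScan(st$gm, st$ped))
    expect_identical(sum(ps$nErrors), nrow(st$errors))
  }
})

test_that("observed informative fractions track the model at p = 0.5", {
  # the independence model is exact at maximal heterozygosity
  st <- simulateTrioGenotypes(nTrios = 400, nSites = 250,
                              mafRange = c(0.5, 0.5), seed = 53)
  ps <- perSite(mendelScan(st$gm, st$ped))
  obs <- mean(ps$nInformative / ps$nComplete)
  expect_lt(abs(obs - 0.875), 0.01)
  # model column is evaluated at the estimated MAF, which hovers near 0.5
  expect_equal(mean(ps$expectedInformative), 0.875, tolerance = 1e-3)
})

test_that("per-site error counts never exceed informative counts", {
  st <- simulateTrioGenotypes(nTrios = 100, nSites = 400, errorRate = 0.05,
                              seed = 54)
  ps <- perSite(mendelScan(st$gm, st$ped))
  expect_true(all(ps$nErrors <= ps$nInformative))
  expect_true(all(ps$nInformative <= ps$nComplete))
})

test_that("unresolvable pedigrees are refused", {
  st <- simulateTrioGenotypes(nTrios = 5, nSites = 10, seed = 55)
  bad <- data.frame(id = "x", sire = "y", dam = "z")
  expect_error(mendelScan(st$gm, bad), "no resolvable trios")
})

test_that("site and sample removal rules use strict thresholds", {
  st <- simulateTrioGenotypes(nTrios = 200, nSites = 500, errorRate = 0,
                              seed = 56)
  rep <- mendelScan(st$gm, st$ped)
  fl <- mendelFilter(rep)
  expect_identical(nrow(fl$sites), 0L)     # all rates 0: nothing removed
  expect_length(fl$samples, 0L)
  # plant one sample with errors far above the mean
  m <- calls(st$gm)
  off1 <- st$ped$id[1]
  sites <- which(m[, st$ped$sire[1]] == 0L & m[, st$ped$dam[1]] == 0L)[1:30]
  m[sites, off1] <- 2L
  gm2 <- genotypeCalls(m, chrom = siteInfo(st$gm)$chrom,
                       pos = siteInfo(st$gm)$pos,
                       ref = siteInfo(st$gm)$ref, alt = siteInfo(st$gm)$alt)
  fl2 <- mendelFilter(mendelScan(gm2, st$ped))
  expect_identical(fl2$samples, off1)
})

test_that("a site at exactly the rate threshold is retained", {
  perSite <- data.frame(chrom = "1", pos = c(1L, 2L), maf = 0.3,
                        nComplete = 200L, nInformative = 200L,
                        nErrors = c(1L, 3L),
                        errorRate = c(0.005, 0.015),
                        expectedInformative = 0.7)
  perSample <- data.frame(sample = "o", nTrios = 1L, nErrors = 4L,
                          errorRate = 0.01)
  rep <- new("MendelReport", perSite = perSite, perSample = perSample,
             nTrios = 1L)
  fl <- mendelFilter(rep, siteRateThreshold = 0.005)
  expect_identical(fl$sites$pos, 2L)       # 0.005 itself survives
})

test_that("the advisory inflection estimator lands in the outlier shoulder", {
  # 450 clean sites and 50 high-error sites: the bend is between them
  set.seed(57)
  rates <- c(runif(450, 0, 0.002), runif(50, 0.05, 0.1))
  perSite <- data.frame(chrom = "1", pos = seq_along(rates), maf = 0.3,
                        nComplete = 100L, nInformative = 100L,
                        nErrors = 0L, errorRate = rates,
                        expectedInformative = 0.7)
  rep <- new("MendelReport", perSite = perSite,
             perSample = data.frame(sample = "o", nTrios = 1L,
                                    nErrors = 0L, errorRate = 0),
             nTrios = 1L)
  thr <- suggestSiteThreshold(rep)
  expect_gt(thr, 0.002)
  expect_lt(thr, 0.05)
  emptySample <- data.frame(sample = character(), nTrios = integer(),
                            nErrors = integer(), errorRate = numeric())
  expect_true(is.na(suggestSiteThreshold(
    new("MendelReport", perSite = perSite[0, ],
        perSample = emptySample, nTrios = 0L))))
})
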