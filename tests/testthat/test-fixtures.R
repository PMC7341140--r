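cat_ <- enzymeCatalog()

test_that("generated genomes are byte-identical under a fixed seed", {
  g1 <- makeGenome(3e4, inserts = rep(150L, 3), seed = 81)
  g2 <- makeGenome(3e4, inserts = rep(150L, 3), seed = 81)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$fragments, g2$fragments)
  g3 <- makeGenome(3e4, inserts = rep(150L, 3), seed = 82)
  expect_false(identical(as.character(g1$genome), as.character(g3$genome)))
})

test_that("the truth table matches the actual digest exactly", {
  gx <- makeGenome(6e4, inserts = c(130L, 180L, 260L, 300L), seed = 83)
  fr <- digestGenome(gx$genome, cat_$PstI, cat_$NlaIII)
  ps <- fr[S4Vectors::mcols(fr)$endClass == "PS"]
  expect_identical(sort(BiocGenerics::start(ps) - 1L),
                   sort(gx$fragments$start))
  expect_identical(sort(BiocGenerics::end(ps)), sort(gx$fragments$end))
  expect_identical(sort(BiocGenerics::width(ps)),
                   sort(gx$fragments$length))
  # every recorded cut is a real fragment boundary
  bounds <- sort(unique(c(BiocGenerics::start(fr) - 1L,
                          BiocGenerics::end(fr))))
  expect_true(all(gx$cuts$pos %in% bounds))
})

test_that("a siteless genome digests to a single terminal fragment", {
  gx <- makeGenome(1e4, seed = 84)
  fr <- digestGenome(gx$genome, cat_$PstI, cat_$NlaIII)
  expect_length(fr, 1L)
  expect_identical(BiocGenerics::width(fr), 10000L)
  expect_identical(nrow(gx$fragments), 0L)
})

test_that("infeasible packings are refused", {
  expect_error(makeGenome(1500, inserts = rep(200L, 5), seed = 85),
               "infeasible packing")
  expect_error(makeGenome(5e4, inserts = 3L, seed = 86),
               "infeasible packing|too short")
})

test_that("read simulation is deterministic and truth-complete", {
  gx <- makeGenome(4e4, inserts = rep(200L, 3), seed = 87)
  bt <- barcodeTable(c("s1", "s2"), c("ACGT", "GGTCAA"))
  s1 <- simulateGbsReads(gx, bt, readsPerSample = 10, seed = 88)
  s2 <- simulateGbsReads(gx, bt, readsPerSample = 10, seed = 88)
  expect_identical(as.character(s1$reads), as.character(s2$reads))
  expect_identical(s1$truth, s2$truth)
  expect_identical(nrow(s1$truth), 20L)
  # layout: barcode + residual + insert prefix
  expect_true(all(substr(as.character(s1$reads)[1:10], 1, 4) == "ACGT"))
  expect_true(all(substr(as.character(s1$reads)[1:10], 5, 9) == "TGCAG"))
})

test_that("trio simulation is deterministic and honours its MAF range", {
  s1 <- simulateTrioGenotypes(nTrios = 30, nSites = 100, seed = 89)
  s2 <- simulateTrioGenotypes(nTrios = 30, nSites = 100, seed = 89)
  expect_identical(calls(s1$gm), calls(s2$gm))
  expect_true(all(s1$maf >= 0.05 & s1$maf <= 0.5))
  expect_identical(dim(calls(s1$gm)), c(100L, 90L))
})

test_that("read-count simulation is deterministic and sums per sample", {
  sex <- c(a = "F", b = "M")
  r1 <- simulateReadcountTables(sex, seed = 90)
  r2 <- simulateReadcountTables(sex, seed = 90)
  expect_identical(r1, r2)
  tot <- tapply(r1$mapped, r1$sample, sum)
  expect_identical(as.numeric(tot[c("a", "b")]), c(1e6, 1e6))
})
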