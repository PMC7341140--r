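bt2 <- barcodeTable(c("s1", "s2"), c("ACGT", "TGCA"))

test_that("exact-match reads are assigned and barcode-trimmed", {
  rd <- makeReads(c(r1 = paste0("ACGT", "TGCAG", strrep("A", 40))))
  dr <- demultiplexReads(rd, bt2)
  expect_identical(sampleCounts(dr), c(s1 = 1L, s2 = 0L))
  emitted <- as.character(dr@reads$s1[[1]])
  expect_identical(substr(emitted, 1, 5), "TGCAG")  # residual retained
  expect_identical(nchar(emitted), 45L)
})

test_that("one barcode mismatch is tolerated, two are not", {
  rd <- makeReads(c(
    mm1 = paste0("ACGA", "TGCAG", strrep("C", 40)),   # 1 mismatch vs ACGT
    mm2 = paste0("AGGA", "TGCAG", strrep("C", 40))))  # 2 mismatches
  dr <- demultiplexReads(rd, barcodeTable("s1", "ACGT"))
  expect_identical(sampleCounts(dr), c(s1 = 1L))
  expect_identical(dr@unassigned, 1L)
})

test_that("reads equidistant from two barcodes are ambiguous and discarded", {
  # ACGG is distance 1 from both ACGT and ACGC
  bt <- barcodeTable(c("a", "b"), c("ACGT", "ACGC"))
  rd <- makeReads(c(r = paste0("ACGG", "TGCAG", strrep("T", 30))))
  dr <- demultiplexReads(rd, bt)
  expect_identical(dr@ambiguous, 1L)
  expect_identical(sum(sampleCounts(dr)), 0L)
})

test_that("a longer barcode wins over a shorter one at equal distance", {
  bt <- barcodeTable(c("short", "long"), c("ACGT", "ACGTA"))
  # read matches both exactly over their own lengths; the 5-mer must win
  rd <- makeReads(c(r = paste0("ACGTA", "TGCAG", strrep("G", 30))))
  dr <- demultiplexReads(rd, bt)
  expect_identical(sampleCounts(dr)[["long"]], 1L)
  expect_identical(sampleCounts(dr)[["short"]], 0L)
})

test_that("a wrong cut-site residual is counted no-residual, never assigned", {
  rd <- makeReads(c(r = paste0("ACGT", "TGCAA", strrep("A", 30))))
  dr <- demultiplexReads(rd, bt2)
  expect_identical(dr@noResidual, 1L)
  expect_identical(sum(sampleCounts(dr)), 0L)
})

test_that("read conservation holds and counts are order-independent", {
  cat_ <- enzymeCatalog()
  gx <- makeGenome(5e4, inserts = rep(200L, 3), seed = 21)
  bt <- barcodeTable(c("s1", "s2", "s3"), c("ACGT", "GGTCAA", "TTACGGCA"))
  sim <- simulateGbsReads(gx, bt, readsPerSample = 25, seed = 22)
  # corrupt a few reads so every category is populated
  raw <- as.character(sim$reads)
  raw[1] <- paste0("CCCC", substr(raw[1], 5, nchar(raw[1])))      # unassigned
  raw[2] <- paste0(substr(raw[2], 1, 4), "AAAAA",
                   substr(raw[2], 10, nchar(raw[2])))             # no residual
  rd <- makeReads(setNames(raw, names(sim$reads)))
  dr <- demultiplexReads(rd, bt)
  expect_identical(sum(sampleCounts(dr)) + dr@unassigned +
                     dr@noResidual + dr@ambiguous, length(rd))
  # shuffling the input changes no per-sample count
  set.seed(9)
  dr2 <- demultiplexReads(rd[sample(length(rd))], bt)
  expect_identical(sampleCounts(dr2), sampleCounts(dr))
  expect_identical(dr2@unassigned, dr@unassigned)
})

test_that("simulated reads round-trip: 100% at 0 and 1 mismatches, 0% at 2", {
  gx <- makeGenome(5e4, inserts = rep(200L, 3), seed = 31)
  bt <- barcodeTable(c("s1", "s2", "s3"), c("ACGT", "GGTCAA", "TTACGGCA"))
  for (mm in 0:1) {
    sim <- simulateGbsReads(gx, bt, readsPerSample = 40,
                            barcodeMismatches = mm, seed = 32 + mm)
    dr <- demultiplexReads(sim$reads, bt, keepReads = FALSE)
    expect_identical(sum(sampleCounts(dr)), nrow(sim$truth))
    expect_identical(as.integer(sampleCounts(dr)[c("s1", "s2", "s3")]),
                     as.integer(table(sim$truth$sample)[c("s1", "s2", "s3")]))
  }
  sim2 <- simulateGbsReads(gx, bt, readsPerSample = 40,
                           barcodeMismatches = 2, seed = 35)
  dr2 <- demultiplexReads(sim2$reads, bt, keepReads = FALSE)
  expect_identical(sum(sampleCounts(dr2)), 0L)
})

test_that("ambiguity-prone barcode tables are rejected at load", {
  # "ACGT" + residual "TGCAG..." begins with "ACGTT": masks barcode ACGTT
  expect_error(barcodeTable(c("a", "b"), c("ACGT", "ACGTT")), "masks")
  expect_error(barcodeTable(c("a", "a"), c("ACGT", "GGCC")), "unique")
  expect_error(barcodeTable(c("a", "b"), c("ACGT", "ACGT")), "unique")
})

test_that("per-sample read thresholds use an inclusive boundary", {
  dr <- new("DemuxResult",
            sampleCounts = c(a = 1999999L, b = 2000000L, c = 0L),
            unassigned = 0L, noResidual = 0L, ambiguous = 0L,
            total = 3999999L, reads = list())
  th <- applySampleThreshold(dr)
  expect_identical(setNames(th$pass, th$sample),
                   c(a = FALSE, b = TRUE, c = FALSE))
  thAll <- applySampleThreshold(
    new("DemuxResult", sampleCounts = c(a = 0L, b = 0L), unassigned = 0L,
        noResidual = 0L, ambiguous = 0L, total = 0L, reads = list()))
  expect_true(all(!thAll$pass))
  expect_identical(nrow(thAll), 2L)
})

test_that("demultiplexing writes per-sample FASTQ when asked", {
  gx <- makeGenome(5e4, inserts = rep(200L, 2), seed = 41)
  bt <- barcodeTable(c("s1", "s2"), c("ACGT", "GGTCAA"))
  sim <- simulateGbsReads(gx, bt, readsPerSample = 5, seed = 42)
  dir <- withr::local_tempdir()
  dr <- demultiplexReads(sim$reads, bt, outDir = dir)
  f <- file.path(dir, "s1.fastq")
  expect_true(file.exists(f))
  back <- readFastq(f)
  expect_length(back, 5L)
  expect_true(all(startsWith(as.character(back), "TGCAG")))
})
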