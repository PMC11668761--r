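test_that("the .bed codec decodes published byte patterns", {
  # 4 samples, 1 SNP, payload byte 0x1B: bit pairs from LSB are
  # 11, 10, 01, 00 -> dosages 2, 1, NA, 0
  prefix <- tempfile()
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x1b)), paste0(prefix, ".bed"))
  writeLines("1\tsnp1\t0\t100\tA\tG", paste0(prefix, ".bim"))
  writeLines(sprintf("F%d\tS%d\t0\t0\t1\t-9", 1:4, 1:4),
             paste0(prefix, ".fam"))
  g <- readPlink(prefix)
  expect_equal(as.vector(dosageMatrix(g)), c(2L, 1L, NA, 0L))
  expect_equal(snpInfo(g)$a2, "G")
})

test_that("write/read round-trips cover byte-boundary sample counts", {
  set.seed(31)
  for (n in 1:5) {
    for (m in c(1L, 3L)) {
      d <- matrix(sample(c(0L, 1L, 2L, NA), n * m, replace = TRUE), n, m)
      g <- genotypeMatrix(d)
      prefix <- tempfile()
      writePlink(g, prefix)
      back <- readPlink(prefix)
      expect_identical(dosageMatrix(back), dosageMatrix(g))
      expect_equal(snpInfo(back)$id, snpInfo(g)$id)
      expect_equal(sampleInfo(back)$iid, sampleInfo(g)$iid)
    }
  }
  # empty-variant fileset
  g0 <- genotypeMatrix(matrix(integer(), 3L, 0L))
  prefix <- tempfile()
  writePlink(g0, prefix)
  expect_equal(ncol(dosageMatrix(readPlink(prefix))), 0L)
})

test_that("the .bed writer emits spec-conformant byte patterns", {
  # an all-missing SNP is a run of 01 bit pairs (0x55)
  g <- genotypeMatrix(matrix(NA_integer_, 4L, 1L))
  prefix <- tempfile()
  writePlink(g, prefix)
  raw <- readBin(paste0(prefix, ".bed"), "raw", 10)
  expect_identical(raw[1:3], as.raw(c(0x6c, 0x1b, 0x01)))
  expect_identical(raw[4], as.raw(0x55))
  # n = 1: one byte per SNP, padding bits zero
  g1 <- genotypeMatrix(matrix(2L, 1L, 2L))
  writePlink(g1, prefix)
  raw1 <- readBin(paste0(prefix, ".bed"), "raw", 10)
  expect_identical(raw1[4:5], as.raw(c(0x03, 0x03)))
})

test_that("corrupt PLINK filesets are rejected", {
  prefix <- tempfile()
  writeLines("1\tsnp1\t0\t100\tA\tG", paste0(prefix, ".bim"))
  writeLines("F1\tS1\t0\t0\t1\t-9", paste0(prefix, ".fam"))
  writeBin(as.raw(c(0x00, 0x1b, 0x01, 0x00)), paste0(prefix, ".bed"))
  expect_error(readPlink(prefix), "magic")
  writeBin(as.raw(c(0x6c, 0x1b, 0x00, 0x00)), paste0(prefix, ".bed"))
  expect_error(readPlink(prefix), "SNP-major")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x00, 0x00)), paste0(prefix, ".bed"))
  expect_error(readPlink(prefix), "does not match")
})

test_that("allele statistics handle missingness and symmetry", {
  g <- genotypeMatrix(cbind(c(0L, 1L, 2L, 2L), c(0L, 0L, 0L, 0L),
                            c(NA, 1L, 1L, NA)))
  s1 <- alleleStats(g, 1)
  expect_equal(s1$a2Freq, 5 / 8)
  expect_equal(s1$maf, 0.375)
  expect_equal(s1$callRate, 1)
  expect_equal(unname(s1$counts), c(1L, 1L, 2L))
  expect_equal(alleleStats(g, 2)$maf, 0)
  s3 <- alleleStats(g, 3)
  expect_equal(s3$callRate, 0.5)
  expect_equal(s3$maf, 0.5)
  # maf invariant under allele swap (dosage complementation)
  set.seed(12)
  d <- matrix(sample(c(0:2, NA), 60, replace = TRUE), 20L)
  gS <- genotypeMatrix(d); gC <- genotypeMatrix(2L - d)
  for (j in 1:3)
    expect_equal(alleleStats(gS, j)$maf, alleleStats(gC, j)$maf)
  # all-missing SNP flagged with NA maf
  expect_true(is.na(alleleStats(genotypeMatrix(matrix(NA_integer_, 4, 1)),
                                1)$maf))
})

test_that("the HWE exact test agrees with the enumeration oracle", {
  expect_equal(hweExact(5, 0, 0), 1)
  expect_equal(hweExact(0, 1, 0), 1)
  expect_error(hweExact(-1, 0, 2), "non-negative")
  maxDiff <- 0
  for (n in 1:16) for (n0 in 0:n) for (n1 in 0:(n - n0)) {
    n2 <- n - n0 - n1
    maxDiff <- max(maxDiff, abs(hweExact(n0, n1, n2) - hweOracle(n0, n1, n2)))
  }
  expect_lt(maxDiff, 1e-12)
  # a strong heterozygote excess is rejected
  expect_lt(hweExact(0, 40, 0), 1e-6)
})

test_that("QC filtering applies the documented order and is idempotent", {
  # 30 samples x 12 SNPs with exactly one violation per filter:
  # s1 multi-character allele; s2 28% missing after sample removal; s3
  # monomorphic; s4 total heterozygote deficit (HWE); s5, s6 clean except
  # for calls missing in the high-missingness sample; s7..s12 fully clean
  clean <- rep(c(0L, 1L, 2L, 1L, 0L, 1L), 5L)
  cleanNA1 <- clean; cleanNA1[1L] <- NA
  s2 <- clean; s2[2:9] <- NA
  d <- cbind(rep(1L, 30), s2, rep(0L, 30), rep(c(0L, 2L), 15L),
             cleanNA1, cleanNA1,
             clean, clean, clean, clean, clean, clean)
  snps <- data.frame(chrom = "1", id = sprintf("s%d", 1:12), cm = 0,
                     pos = 1:12, a1 = c("AT", rep("A", 11L)),
                     a2 = "G", stringsAsFactors = FALSE)
  g <- genotypeMatrix(d, snps = snps)
  qc <- qcFilter(g)
  expect_equal(qc$report$removed, rep(1L, 5L))
  expect_equal(attr(qc$report, "m"), 8L)
  expect_equal(attr(qc$report, "n"), 29L)
  expect_equal(snpInfo(qc$genotypes)$id, sprintf("s%d", 5:12))
  # removed + surviving reconcile per axis
  snpRemoved <- sum(qc$report$removed[qc$report$axis == "snp"])
  expect_equal(snpRemoved + attr(qc$report, "m"), attr(qc$report, "mInput"))
  # idempotent
  qc2 <- qcFilter(qc$genotypes)
  expect_equal(dosageMatrix(qc2$genotypes), dosageMatrix(qc$genotypes))
  expect_equal(sum(qc2$report$removed), 0L)
})

test_that("genetic PCs are orthonormal and expose population structure", {
  cfg <- simConfig(n = 120L, m = 80L, missingRate = 0.02,
                   populationStructure = 0.25, seed = 17)
  g <- simulateGenotypes(cfg)
  pcs <- geneticPCs(g, 5L)
  expect_equal(dim(pcs), c(120L, 5L))
  expect_lt(max(abs(crossprod(pcs) - diag(5))), 1e-8)
  groups <- attr(g, "groups")
  # PC1 separates the two subpopulations with no overlap
  expect_true(max(pcs[groups == 0L, 1]) < min(pcs[groups == 1L, 1]) ||
                min(pcs[groups == 0L, 1]) > max(pcs[groups == 1L, 1]))
  # duplicating every sample duplicates its score row
  d <- dosageMatrix(g)
  gDup <- genotypeMatrix(rbind(d, d))
  pcsDup <- geneticPCs(gDup, 3L)
  expect_equal(pcsDup[1:120, ], pcsDup[121:240, ], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(geneticPCs(g, 200L), "smaller")
})
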