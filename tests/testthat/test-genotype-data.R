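test_that("GenotypeStudy validates its contents", {
  g <- matrix(c(0L, 1L, 2L, 0L), 2, 2)
  s <- GenotypeStudy(g, c(1, -1))
  expect_s4_class(s, "GenotypeStudy")
  expect_equal(nSnps(s), 2L)
  expect_equal(nSubjects(s), 2L)
  expect_equal(nCases(s), 1L)
  expect_equal(nControls(s), 1L)
  expect_error(GenotypeStudy(matrix(3L, 1, 1), 1), "0, 1, 2")
  expect_error(GenotypeStudy(g, c(1, 0)), "coded")
  bad <- S4Vectors::DataFrame(snp_id = c("a", "a"), chromosome = "1",
                              position = 1:2, allele_major = "A",
                              allele_minor = "B")
  expect_error(GenotypeStudy(g, c(1, -1), snpInfo = bad), "unique")
})

test_that("binary encoding is one-hot per non-missing genotype", {
  g <- matrix(c(0L, 2L, 1L, NA), nrow = 2)   # 2 SNPs x 2 subjects
  enc <- encodeBinary(makeStudy(g, c(1, -1)))@encoding
  expect_equal(enc[1, blockColumns(1)], c(1, 0, 0))  # count 0
  expect_equal(enc[1, blockColumns(2)], c(0, 0, 1))  # count 2
  expect_equal(enc[2, blockColumns(1)], c(0, 1, 0))  # count 1
  expect_equal(enc[2, blockColumns(2)], c(0, 0, 0))  # missing
  # block sums: 1 iff non-missing, so a fully typed row sums to d
  expect_equal(sum(enc[1, ]), 2)
  expect_equal(sum(enc[2, ]), 1)
})

test_that("contingency tables count correctly and drop missing calls", {
  g <- matrix(c(rep(0L, 4), rep(2L, 4)), nrow = 1)
  s <- makeStudy(g, c(rep(1, 4), rep(-1, 4)))
  expect_equal(unname(buildContingencyTable(s, 1)),
               matrix(c(4L, 0L, 0L, 0L, 0L, 4L), 2, 3))
  g2 <- matrix(c(0L, 1L, NA, 2L, 1L, 0L), nrow = 1)
  s2 <- makeStudy(g2, c(1, 1, 1, -1, -1, -1))
  tab <- buildContingencyTable(s2, 1)
  expect_equal(sum(tab), 5L)                 # missing call excluded
  expect_equal(unname(rowSums(tab)), c(2L, 3L))
  # empty category is a zero cell, not an error
  expect_equal(tab[, "2"], c(case = 0L, control = 1L))
})

test_that("plink text round trip is the identity", {
  sim <- quickSim(seed = 5, n = 30, d = 12)
  st <- sim$study
  # add a missing call and a monomorphic-ish column to exercise edge paths
  g <- genotypes(st); g[3, 7] <- NA
  st <- GenotypeStudy(g, phenotypes(st), snpInfo = snpInfo(st))
  base <- file.path(tempdir(), "rt")
  writePlinkText(st, base)
  back <- readPlinkText(paste0(base, ".ped"), paste0(base, ".map"))
  expect_equal(unname(genotypes(back)), unname(genotypes(st)))
  expect_equal(phenotypes(back), phenotypes(st))
  expect_equal(snpInfo(back)$snp_id, snpInfo(st)$snp_id)
  expect_equal(snpInfo(back)$position, snpInfo(st)$position)
})

test_that("plink reader maps alleles to minor-allele counts", {
  dir <- tempdir()
  ped <- file.path(dir, "toy.ped"); map <- file.path(dir, "toy.map")
  writeLines(c("f1 i1 0 0 0 2 A A",
               "f2 i2 0 0 0 1 A G"), ped)
  writeLines("1\trs1\t0\t100", map)
  st <- readPlinkText(ped, map)
  # G is the minor allele (freq 1/4): counts (0, 1); case first
  expect_equal(unname(genotypes(st)[1, ]), c(0L, 1L))
  expect_equal(phenotypes(st), c(1L, -1L))
  expect_equal(snpInfo(st)$allele_minor, "G")

  # .map declaring fewer SNPs than the .ped carries -> format error
  writeLines(c("f1 i1 0 0 0 2 A A G G",
               "f2 i2 0 0 0 1 A G A A"), ped)
  expect_error(readPlinkText(ped, map), "mismatch")

  # bad phenotype code -> error; 0/-9 dropped with warning
  writeLines(c("f1 i1 0 0 0 7 A A"), ped)
  expect_error(readPlinkText(ped, map), "phenotype")
  writeLines(c("f1 i1 0 0 0 2 A G",
               "f2 i2 0 0 0 -9 A A",
               "f3 i3 0 0 0 1 G G"), ped)
  expect_warning(st2 <- readPlinkText(ped, map), "dropping 1 subject")
  expect_equal(nSubjects(st2), 2L)
})

test_that("vcf reader honors GT codes and minor-allele orientation", {
  dir <- tempdir()
  vcf <- file.path(dir, "toy.vcf"); tsv <- file.path(dir, "pheno.tsv")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/1\t0/0\t./.",
    "1\t200\trs2\tT\tC\t.\tPASS\t.\tGT\t1/1\t1/1\t0/1",
    "1\t300\trs3\tA\tC,G\t.\tPASS\t.\tGT\t0/1\t0/0\t0/0"), vcf)
  writeLines(c("sample_id\tphenotype", "S1\t2", "S2\t1", "S3\t2"), tsv)
  expect_warning(st <- readVcf(vcf, tsv), "multi-allelic")
  expect_equal(nSnps(st), 2L)                       # rs3 skipped
  expect_equal(unname(genotypes(st)[1, ]), c(1L, 0L, NA))
  # rs2: ALT frequency 5/6 > 0.5 -> re-oriented to count REF
  expect_equal(unname(genotypes(st)[2, ]), c(0L, 0L, 1L))
  expect_equal(snpInfo(st)$allele_minor[2], "T")
  expect_equal(phenotypes(st), c(1L, -1L, 1L))

  writeLines(c("sample_id\tphenotype", "S1\t2", "S2\t1"), tsv)
  expect_error(suppressWarnings(readVcf(vcf, tsv)), "absent")
})

test_that("study cache round-trips and rejects foreign versions", {
  st <- quickSim(seed = 2, n = 20, d = 6)$study
  path <- file.path(tempdir(), "study.rds")
  writeStudyCache(st, path)
  expect_equal(genotypes(readStudyCache(path)), genotypes(st))
  saveRDS(list(version = "other", study = st), path)
  expect_error(readStudyCache(path), "version")
})
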