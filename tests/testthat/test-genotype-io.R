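test_that("PED parsing follows the het/hom and missing-allele rules", {
  dir <- withr::local_tempdir()
  writeLines(c("1\tsnp1\t0\t100", "1\tsnp2\t0\t200", "1\tsnp3\t0\t300"),
             file.path(dir, "x.map"))
  writeLines("FAM1 ind1 0 0 0 -9 A A G T 0 A",
             file.path(dir, "x.ped"))
  ds <- read_ped_map(file.path(dir, "x.ped"), file.path(dir, "x.map"))
  # snp1: A/A hom for the lexicographically smaller allele -> dosage 0
  # snp2: G/T het -> 1; snp3: one allele "0" -> missing
  expect_equal(as.vector(ds$calls), c(0L, 1L, NA_integer_))
  expect_equal(ds$samples$population, "FAM1")
  # snp1 is monomorphic and snp3 has no complete call: counted allele "0"
  expect_equal(ds$snps$allele_a, c("A", "G", "0"))
  expect_equal(ds$snps$allele_b, c("0", "T", "0"))
})

test_that("PED rows with the wrong column count raise a format error", {
  dir <- withr::local_tempdir()
  writeLines(c("1\tsnp1\t0\t100", "1\tsnp2\t0\t200"), file.path(dir, "x.map"))
  writeLines(c("F1 i1 0 0 0 -9 A A G G",
               "F1 i2 0 0 0 -9 A A G"), file.path(dir, "x.ped"))
  expect_error(read_ped_map(file.path(dir, "x.ped"), file.path(dir, "x.map")),
               "row 2")
})

test_that("duplicate snp ids in the MAP raise a format error", {
  dir <- withr::local_tempdir()
  writeLines(c("1\tsnp1\t0\t100", "1\tsnp1\t0\t200"), file.path(dir, "x.map"))
  writeLines("F1 i1 0 0 0 -9 A A G G", file.path(dir, "x.ped"))
  expect_error(read_ped_map(file.path(dir, "x.ped"), file.path(dir, "x.map")),
               "duplicate")
})

test_that("PED/MAP round-trips exactly, with fixed het order and 0 0 missing", {
  ds <- random_dataset(5, 40, missing = 0.1, seed = 3, n_chrom = 2)
  dir <- withr::local_tempdir()
  write_ped_map(ds, file.path(dir, "rt.ped"), file.path(dir, "rt.map"))
  ped <- readLines(file.path(dir, "rt.ped"))
  # het written as (allele_a, allele_b); hom_alt as allele_b twice
  f <- strsplit(ped[1], " ")[[1]]
  g1 <- ds$calls[1, ]
  het_j <- which(!is.na(g1) & g1 == 1L)[1]
  expect_equal(f[6 + 2 * het_j - 1], "A")
  expect_equal(f[6 + 2 * het_j], "B")
  hom_j <- which(!is.na(g1) & g1 == 2L)[1]
  expect_equal(f[6 + 2 * hom_j - 1], "B")
  mis_j <- which(is.na(g1))[1]
  expect_equal(f[6 + 2 * mis_j - 1], "0")

  back <- read_ped_map(file.path(dir, "rt.ped"), file.path(dir, "rt.map"))
  expect_equal(back$calls, ds$calls)
  expect_equal(back$snps$bp_pos, ds$snps$bp_pos)
  expect_equal(back$snps$snp_id, ds$snps$snp_id)
  expect_equal(back$samples, ds$samples)
})

test_that("BED bit decoding matches the PLINK 1 two-bit spec", {
  dir <- withr::local_tempdir()
  writeLines("1\tsnp1\t0\t100\tB\tA", file.path(dir, "x.bim"))
  writeLines(sprintf("F%d\ti%d\t0\t0\t0\t-9", 1:4, 1:4), file.path(dir, "x.fam"))
  con <- file(file.path(dir, "x.bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0xE4)), con)  # 0b11100100
  close(con)
  ds <- read_bed_bim_fam(file.path(dir, "x.bed"), file.path(dir, "x.bim"),
                         file.path(dir, "x.fam"))
  # 00 = hom allele1 (counted) -> 2, 01 = missing, 10 = het, 11 = hom allele2
  expect_equal(as.vector(ds$calls), c(2L, NA_integer_, 1L, 0L))
})

test_that("BED round-trips and agrees with the PED dialect", {
  ds <- random_dataset(7, 55, missing = 0.08, seed = 9, n_chrom = 2)
  # force every SNP polymorphic: PED carries no counted-allele identity for
  # monomorphic SNPs, so cross-dialect equality only holds when both alleles
  # are observed (the monomorphic normalization is tested above)
  ds$calls[1, ] <- 0L
  ds$calls[2, ] <- 2L
  dir <- withr::local_tempdir()
  write_bed_bim_fam(ds, file.path(dir, "rt.bed"), file.path(dir, "rt.bim"),
                    file.path(dir, "rt.fam"))
  back <- read_bed_bim_fam(file.path(dir, "rt.bed"), file.path(dir, "rt.bim"),
                           file.path(dir, "rt.fam"))
  expect_equal(back$calls, ds$calls)
  expect_equal(back$snps, ds$snps)

  write_ped_map(ds, file.path(dir, "rt.ped"), file.path(dir, "rt.map"))
  from_ped <- read_ped_map(file.path(dir, "rt.ped"), file.path(dir, "rt.map"))
  expect_equal(from_ped$calls, back$calls)
  expect_equal(from_ped$snps$bp_pos, back$snps$bp_pos)
  expect_equal(from_ped$samples, back$samples)
})

test_that("malformed binary inputs are rejected", {
  dir <- withr::local_tempdir()
  writeLines("1\tsnp1\t0\t100\tB\tA", file.path(dir, "x.bim"))
  writeLines("F1\ti1\t0\t0\t0\t-9", file.path(dir, "x.fam"))
  con <- file(file.path(dir, "bad.bed"), "wb")
  writeBin(as.raw(c(0x00, 0x1b, 0x01, 0x00)), con)
  close(con)
  expect_error(read_bed_bim_fam(file.path(dir, "bad.bed"),
                                file.path(dir, "x.bim"),
                                file.path(dir, "x.fam")), "magic")

  con <- file(file.path(dir, "short.bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  close(con)
  expect_error(read_bed_bim_fam(file.path(dir, "short.bed"),
                                file.path(dir, "x.bim"),
                                file.path(dir, "x.fam")), "bytes")

  writeLines(character(0), file.path(dir, "empty.fam"))
  con <- file(file.path(dir, "x.bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x00)), con)
  close(con)
  expect_error(read_bed_bim_fam(file.path(dir, "x.bed"),
                                file.path(dir, "x.bim"),
                                file.path(dir, "empty.fam")), "no samples")
})
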