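test_that("VCF write-then-read is the identity on content", {
  gm <- toy_gm()
  path <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes(gm, path, "vcf")
  back <- read_genotypes(path, "vcf")
  expect_identical(back$samples, gm$samples)
  expect_identical(back$calls, gm$calls)
  expect_identical(back$snps[, names(gm$snps)], gm$snps)
})

test_that("tabular write-then-read is the identity on content", {
  gm <- toy_gm()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(gm, path, "tab")
  back <- read_genotypes(path, "tab")
  expect_identical(back$calls, gm$calls)
  expect_identical(back$snps, gm$snps)
})

test_that("GT parsing follows the format: dosage of ALT, ./. missing", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsmpA\tsmpB",
    "chr1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1",
    "chr1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t./.\t1|1"
  ), path)
  gm <- read_genotypes(path, "vcf")
  expect_equal(unname(gm$calls[, "rs1"]), c(0L, 1L))
  expect_equal(unname(gm$calls[, "rs2"]), c(NA_integer_, 2L))
})

test_that("multi-allelic records are rejected in strict mode, dropped otherwise", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "chr1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/1",
    "chr1\t200\trs2\tC\tG,T\t.\tPASS\t.\tGT\t0/0"
  ), path)
  expect_error(read_genotypes(path, "vcf", strict = TRUE), "non-biallelic")
  expect_warning(gm <- read_genotypes(path, "vcf", strict = FALSE), "dropping")
  expect_equal(gm$snps$snp_id, "rs1")
})

test_that("phenotype reader enforces schema, plausibility band and unique ids", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_fixture(data.frame(sample_id = c("S1", "S2", "S3"),
                               melanin_index = c(31.0, 500, 28.2),
                               sex = c(1L, 0L, 0L)), path)
  expect_warning(ph <- read_phenotypes(path), "implausible")
  expect_equal(ph$sample_id, c("S1", "S3"))
  expect_equal(ph$melanin_index, c(31.0, 28.2))

  write_tsv_fixture(data.frame(sample_id = c("S1", "S1"),
                               melanin_index = c(31, 30), sex = c(0L, 1L)),
                    path)
  expect_error(read_phenotypes(path), "duplicate")

  write_tsv_fixture(data.frame(sample_id = "S1", sex = 0L), path)
  expect_error(read_phenotypes(path), "melanin_index")
})

test_that("attach_ancestral sets, leaves unknown, and warns on mismatch", {
  gm <- toy_gm()
  gm$snps$ancestral <- NA_character_
  tab <- data.frame(snp_id = c("rs1", "rs3"),
                    ancestral = c("A", "G"),   # G matches neither T/C at rs3
                    stringsAsFactors = FALSE)
  expect_warning(out <- attach_ancestral(gm, tab), "neither observed allele")
  expect_equal(out$snps$ancestral, c("A", NA, NA))
})

test_that("derived frequency equals 1 - ancestral frequency where known", {
  set.seed(11)
  calls <- matrix(rbinom(200, 2, 0.4), nrow = 20)
  snps <- data.frame(snp_id = paste0("rs", 1:10), chrom = "chr1",
                     pos = seq(100, 1000, 100),
                     allele_a = "A", allele_b = "G",
                     ancestral = sample(c("A", "G", NA), 10, replace = TRUE),
                     stringsAsFactors = FALSE)
  gm <- genotype_matrix(paste0("S", 1:20), snps, calls)
  der <- allele_freqs(gm, "derived")
  anc <- allele_freqs(gm, "ancestral")
  known <- !is.na(gm$snps$ancestral)
  expect_equal(der[known], 1 - anc[known])
  expect_true(all(is.na(der[!known])))
})

test_that("BED regions read as 0-based half-open and validate", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr15\t25000000\t25100000\tOCA2",
               "chr13\t94000000\t94040000\tDCT"), path)
  rs <- read_regions(path)
  expect_s3_class(rs, "region_set")
  expect_equal(rs$start, c(25000000L, 94000000L))
  expect_equal(rs$end, c(25100000L, 94040000L))
  expect_error(region_set("r1", "chr1", 10, 10), "start < end")
  expect_error(region_set(c("r", "r"), "chr1", c(0, 5), c(4, 9)), "unique")
})

test_that("haplotype tabular round trip preserves content", {
  hs <- random_hs(10, 6, seed = 3)
  hs$ancestral_code[2] <- NA_integer_
  path <- withr::local_tempfile(fileext = ".tsv")
  write_haplotypes(hs, path)
  back <- read_haplotypes(path, "tab")
  expect_equal(unname(back$haps), unname(hs$haps))
  expect_equal(back$positions, hs$positions)
  expect_equal(back$ancestral_code, hs$ancestral_code)
})

test_that("constructors reject inconsistent input", {
  expect_error(gm_from_calls(c(0, 3)), "0, 1, 2 or NA")
  expect_error(genotype_matrix(c("a", "a"),
                               data.frame(snp_id = "s", chrom = "c", pos = 1,
                                          allele_a = "A", allele_b = "G"),
                               matrix(0L, 2, 1)), "duplicate sample")
  expect_error(haplotype_set(matrix(0:1, 2, 2), "chr1", c(5L, 5L)),
               "strictly increasing")
})
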