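fixture_dir <- withr::local_tempdir(.local_envir = teardown_env())
write_fixture_set(fixture_dir)

test_that("VCF ingestion applies every quality-control filter", {
  gm <- suppressMessages(
    read_vcf_genotypes(file.path(fixture_dir, "filters.vcf")))
  # of 8 records only the clean sites at 100 and 800 survive: missing
  # genotype, triallelic, low QUAL, low MQ, low per-sample DP and
  # excessive site depth each remove one site
  expect_equal(gm$loci$pos, c(100L, 800L))
  expect_equal(gm$loci$dac, c(3L, 3L))
  expect_equal(unname(gm$dosages[, 1]), c(1L, 2L))
  expect_equal(gm$sample_ids, c("s1", "s2"))
})

test_that("three-site VCF with one missing genotype keeps two loci", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  gm0 <- mk_gm(c(0, 1), c(1, 2), c(0, 2))
  gm0$loci$ref <- c("A", "C", "G"); gm0$loci$alt <- c("G", "T", "A")
  write_vcf(gm0, tmp)
  lines <- readLines(tmp)
  i <- grep("^c1\t100\t", lines)
  lines[i] <- sub("0/0:30", "./.:30", lines[i])   # first site, sample 1
  writeLines(lines, tmp)
  gm <- suppressMessages(read_vcf_genotypes(tmp))
  expect_equal(ncol(gm$dosages), 2L)
  expect_equal(gm$loci$pos, c(200L, 300L))
})

test_that("Hardy-Weinberg exact test agrees with the matching oracle", {
  expect_equal(hwe_exact_test(50, 0, 0), 1.0)
  expect_equal(hwe_exact_test(25, 50, 25),
               hwe_matching_oracle(25, 50, 25), tolerance = 1e-12)
  p_split <- hwe_exact_test(50, 0, 50)
  expect_equal(p_split, hwe_matching_oracle(50, 0, 50), tolerance = 1e-10)
  expect_lt(p_split, 1e-6)
  expect_error(hwe_exact_test(0, 0, 0), "all counts zero")

  # brute-force agreement across the configuration space (totals <= 50)
  set.seed(42)
  for (k in 1:60) {
    n <- sample(2:50, 1)
    a <- sample(0:n, 1); b <- sample(0:(n - a), 1); c <- n - a - b
    expect_equal(hwe_exact_test(a, b, c), hwe_matching_oracle(a, b, c),
                 tolerance = 1e-12)
  }
})

test_that("HWE filter removes heterozygote-deficient sites at read time", {
  path <- file.path(fixture_dir, "hwe.vcf")
  gm_all <- suppressMessages(read_vcf_genotypes(path, hwe_p = NULL))
  expect_equal(nrow(gm_all$loci), 3L)
  gm <- suppressMessages(read_vcf_genotypes(path, hwe_p = 1e-6))
  expect_false(200L %in% gm$loci$pos)   # 12 hom-ref / 0 het / 12 hom-alt
  expect_equal(nrow(gm$loci), 2L)
})

test_that("polarisation flips, keeps, drops, and is an involution", {
  gm <- suppressMessages(
    read_vcf_genotypes(file.path(fixture_dir, "filters.vcf")))
  aa <- read_ancestral_tsv(file.path(fixture_dir, "ancestral.tsv"))
  pol <- suppressMessages(polarize_to_derived(gm, aa))
  # site 100: ancestral == REF, unchanged; site 800: ancestral == ALT, flip
  expect_equal(pol$loci$pos, c(100L, 800L))
  expect_equal(unname(pol$dosages[, 1]), c(1L, 2L))
  expect_equal(unname(pol$dosages[, 2]), 2L - unname(gm$dosages[, 2]))
  expect_equal(pol$loci$dac, unname(colSums(pol$dosages)))

  # flipping twice restores the original dosages
  aa_flip <- ancestral_map(c("chr1", "chr1"), c(100L, 800L), c("G", "A"))
  once <- suppressMessages(polarize_to_derived(gm, aa_flip))
  twice <- suppressMessages(polarize_to_derived(once, aa_flip))
  expect_equal(twice$dosages, gm$dosages)

  # unresolvable ancestral alleles drop the loci
  aa_n <- ancestral_map("chr1", 100L, "N")
  none <- suppressMessages(polarize_to_derived(gm, aa_n))
  expect_equal(ncol(none$dosages), 0L)
})

test_that("locus-set selection honours category and dac bounds", {
  X <- cbind(c(1, 0, 0, 0), c(1, 1, 0, 0), c(1, 1, 1, 0), c(2, 2, 2, 0))
  gm <- genotype_matrix(X, data.frame(chrom = "c1", pos = 1:4 * 10L))
  expect_equal(gm$loci$dac, c(1L, 2L, 3L, 6L))
  s <- select_locus_set(gm, mdac = 3, min_dac = 2)
  expect_equal(gm$loci$dac[s$indices], c(2L, 3L))
  s_all <- select_locus_set(gm, min_dac = 2)
  expect_equal(length(s_all), 3L)
  s_f <- select_locus_set(gm, mdaf = 3 / 8, min_dac = 1)
  expect_equal(gm$loci$dac[s_f$indices], c(1L, 2L, 3L))
  expect_error(select_locus_set(gm, mdac = 1), "insufficient loci")
  expect_error(select_locus_set(gm, category = "LoF"), "no category")
})

test_that("annotation ingestion: TSV, CSQ severity ranking, application", {
  ann <- read_annotation_tsv(file.path(fixture_dir, "annotations.tsv"))
  expect_equal(ann$category, c("synonymous", "LoF"))

  # VEP-style CSQ with multiple transcripts: most severe category wins
  tmp <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste0("##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Consequence ",
           "annotations. Format: Allele|Consequence|Gene\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1"), collapse = "\t"),
    "chr1\t10\t.\tA\tG\t99\tPASS\tCSQ=G|synonymous_variant|g1\tGT\t0/1",
    paste0("chr1\t20\t.\tC\tT\t99\tPASS\tCSQ=T|missense_variant|g1,",
           "T|stop_gained&splice_region_variant|g2\tGT\t0/1"),
    "chr1\t30\t.\tG\tA\t99\tPASS\tCSQ=A|intron_variant|g1\tGT\t0/1",
    paste0("chr1\t40\t.\tT\tC\t99\tPASS\tCSQ=C|synonymous_variant|g1,",
           "C|missense_variant|g2\tGT\t0/1")
  ), tmp)
  csq <- read_csq_annotations(tmp)
  expect_equal(csq$category,
               c("synonymous", "LoF", NA_character_, "missense"))

  gm <- mk_gm(c(0, 1), c(1, 2), chrom = "chr1")
  gm$loci$pos <- c(10L, 20L)
  gm2 <- apply_annotations(gm, csq)
  expect_equal(gm2$loci$category, c("synonymous", "LoF"))
})

test_that("genotype matrices round-trip through TSV and VCF", {
  gm <- synth_genotype_matrix(20, dac_spectrum = c(5, 8, 12, 3), seed = 9)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_tsv(gm, tsv)
  back <- read_genotype_tsv(tsv)
  expect_equal(back$dosages, gm$dosages, ignore_attr = TRUE)
  expect_equal(back$loci$dac, gm$loci$dac)

  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, vcf)
  back2 <- suppressMessages(read_vcf_genotypes(vcf))
  expect_equal(unname(back2$dosages), unname(gm$dosages))
  expect_equal(back2$loci$pos, gm$loci$pos)
})
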