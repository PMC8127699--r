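test_that("matrix_csv parsing handles dosages and missing codes", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,L1,L2", "a,0,1", "b,2,NA", "c,1,2"), path)
  g <- read_genotypes(path, "matrix_csv")
  expect_equal(dim(g), c(3L, 2L))
  expect_equal(sum(is.na(g$calls)), 1L)
  expect_equal(g$calls["b", "L1"], 2L)
  expect_equal(g$sample_meta$n_missing, c(0L, 1L, 0L))
})

test_that("VCF GT fields map to alternate-allele dosages and non-SNPs are rejected", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "1\t100\tsnp1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\tindel1\tA\tAT\t.\tPASS\t.\tGT\t0/0\t0/0\t0/0",
    "1\t300\tmulti1\tA\tG,T\t.\tPASS\t.\tGT\t0/0\t0/0\t0/0",
    "1\t400\tsnp2\tC\tT\t.\tPASS\t.\tGT\t1|1\t0|1\t./."), path)
  expect_message(g <- read_genotypes(path, "vcf"), "2 multi-allelic")
  expect_equal(attr(g, "n_rejected"), 2L)
  expect_equal(unname(g$calls[, "snp1"]), c(0L, 1L, 2L))
  expect_equal(unname(g$calls[, "snp2"]), c(2L, 1L, NA))
})

test_that("dart_csv round-trips through write and read identically", {
  set.seed(11)
  spec <- synthetic_spec(n_loci = 40, site_sizes = c(focal = 12),
                         missing_rate = 0.05)
  g <- generate_synthetic(spec, seed = 5)$genotypes
  path <- withr::local_tempfile(fileext = ".csv")
  write_genotypes(g, path, "dart_csv")
  g2 <- read_genotypes(path, "dart_csv")
  expect_identical(g$calls, g2$calls)
  expect_equal(g$locus_meta$reproducibility, g2$locus_meta$reproducibility)
  expect_equal(g$locus_meta$call_rate, g2$locus_meta$call_rate)
  # and round-trip again: stable fixed point
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_genotypes(g2, path2, "dart_csv")
  expect_identical(readLines(path), readLines(path2))
})

test_that("duplicate ids and unknown dosage tokens are hard errors", {
  x <- matrix(0L, 2, 2, dimnames = list(c("a", "a"), c("L1", "L2")))
  expect_error(geno_matrix(x), "duplicate sample ids")
  x <- matrix(0L, 2, 2, dimnames = list(c("a", "b"), c("L1", "L1")))
  expect_error(geno_matrix(x), "duplicate locus ids")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,L1", "a,0", "b,3"), path)
  expect_error(read_genotypes(path, "matrix_csv"), "'3'.*L1")
  x <- matrix(c(0L, 5L), 1, 2, dimnames = list("a", c("L1", "L2")))
  expect_error(geno_matrix(x), "invalid dosage code 5.*'a'.*'L2'")
})

test_that("locus filters apply the exact threshold conventions", {
  x <- matrix(0:2, 10, 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:10), paste0("L", 1:3)))
  lm <- data.frame(locus_id = paste0("L", 1:3),
                   reproducibility = c(0.95, 0.96, 0.97))
  g <- geno_matrix(x, locus_meta = lm)
  # reproducibility strictly greater than the threshold
  gf <- filter_loci(g, reproducibility_min = 0.96, missing_max = NULL)
  expect_equal(locus_ids(gf), "L3")
  expect_equal(filter_report(gf)$removed, 2L)

  # missingness: missing in 2/10 retained, 3/10 removed at 20%
  x2 <- x
  x2[1:2, 1] <- NA
  x2[1:3, 2] <- NA
  g2 <- geno_matrix(x2, locus_meta = lm)
  gf2 <- filter_loci(g2, reproducibility_min = NULL, missing_max = 0.2)
  expect_setequal(locus_ids(gf2), c("L1", "L3"))

  # complete-data filter is the identity on a complete matrix
  gf3 <- filter_loci(g, reproducibility_min = NULL, missing_max = NULL,
                     require_complete = TRUE)
  expect_identical(gf3$calls, g$calls)
  # and removes exactly the loci with any missing call otherwise
  gf4 <- filter_loci(g2, reproducibility_min = NULL, missing_max = NULL,
                     require_complete = TRUE)
  expect_equal(locus_ids(gf4), "L3")

  expect_warning(filter_loci(g, reproducibility_min = 0.99,
                             missing_max = NULL),
                 "all loci removed")
})

test_that("filtering is idempotent", {
  set.seed(21)
  spec <- synthetic_spec(n_loci = 150, site_sizes = c(focal = 25),
                         missing_rate = 0.1, low_repro_frac = 0.3)
  g <- generate_synthetic(spec, seed = 9)$genotypes
  g1 <- filter_loci(g, 0.96, 0.1)
  g2 <- filter_loci(g1, 0.96, 0.1)
  expect_identical(g1$calls, g2$calls)
})

test_that("high-missingness samples are removed by recount", {
  set.seed(31)
  x <- hw_matrix(10, runif(40, 0.2, 0.8))
  x[1, 1:24] <- NA   # 60% missing
  x[2, 1:20] <- NA   # 50% missing: at the threshold, retained
  g <- geno_matrix(x)
  gr <- remove_high_missing_samples(g, 0.5)
  expect_equal(attr(gr, "removed_samples"), "s1")
  # threshold 1 is the identity
  expect_equal(dim(remove_high_missing_samples(g, 1)), dim(g))
  # removal set matches a direct recount at an arbitrary threshold
  frac <- rowMeans(is.na(x))
  gr2 <- remove_high_missing_samples(g, 0.3)
  expect_setequal(attr(gr2, "removed_samples"), names(frac[frac > 0.3]))
})

test_that("allele frequencies ignore missing calls and match a tally oracle", {
  g <- geno_matrix(matrix(c(0L, 1L, 2L), 3, 1,
                          dimnames = list(c("a", "b", "c"), "L1")))
  expect_equal(as.numeric(allele_freqs(g)), 0.5)
  g2 <- geno_matrix(matrix(c(0L, 0L, NA), 3, 1,
                           dimnames = list(c("a", "b", "c"), "L1")))
  expect_equal(as.numeric(allele_freqs(g2)), 0)
  expect_equal(unname(attr(allele_freqs(g2), "n_called")), 2L)

  set.seed(41)
  x <- hw_matrix(20, runif(60, 0.05, 0.95))
  x[sample(length(x), 100)] <- NA
  g3 <- geno_matrix(x)
  f <- allele_freqs(g3)
  manual <- apply(x, 2, function(v) sum(v, na.rm = TRUE) / (2 * sum(!is.na(v))))
  expect_equal(as.numeric(f), unname(manual))

  # zero-call loci are flagged undefined
  x[, 1] <- NA
  g4 <- geno_matrix(x)
  expect_true(is.na(allele_freqs(g4)[1]))
  expect_equal(attr(allele_freqs(g4), "undefined"), "L1")

  expect_error(allele_freqs(g3, character(0)), "empty")
})

test_that("frequencies are invariant to sample and locus permutations", {
  set.seed(51)
  x <- hw_matrix(15, runif(30, 0.1, 0.9))
  g <- geno_matrix(x)
  gs <- subset_geno(g, samples = rev(sample_ids(g)),
                    loci = rev(locus_ids(g)))
  f1 <- allele_freqs(g)
  f2 <- allele_freqs(gs)
  expect_equal(f1[locus_ids(g)], f2[locus_ids(g)])
})

test_that("common loci follow the strict minor-allele-frequency rule", {
  # 18 diploids, one heterozygote: freq 1/36, a singleton, excluded at 3%
  x <- matrix(0L, 18, 1, dimnames = list(paste0("s", 1:18), "L1"))
  x[1, 1] <- 1L
  g <- geno_matrix(x)
  expect_equal(as.numeric(allele_freqs(g)), 1 / 36)
  expect_length(common_loci(g, maf_min = 0.03), 0)
  expect_length(common_loci(g, maf_min = 0.02), 1)  # 2.8% > 2%

  # a monomorphic locus is never common
  g2 <- geno_matrix(matrix(2L, 5, 1, dimnames = list(paste0("s", 1:5), "L1")))
  expect_length(common_loci(g2, maf_min = 0), 0)

  # planted frequencies: set matches a direct computation (folded MAF)
  set.seed(61)
  x3 <- hw_matrix(50, runif(100, 0, 1))
  g3 <- geno_matrix(x3)
  f <- colMeans(x3) / 2
  manual <- colnames(x3)[pmin(f, 1 - f) > 0.1]
  expect_setequal(common_loci(g3, maf_min = 0.1), manual)
})
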