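test_that("error-free ramets are identical to their genet with kinship 0.5", {
  spec <- synthetic_spec(n_loci = 300, site_sizes = c(focal = 10),
                         clone_ramets = c(3L), error_rate = 0,
                         missing_rate = 0)
  out <- generate_synthetic(spec, seed = 601)
  g <- out$genotypes
  ramets <- out$truth$clone_groups[[1]]
  expect_length(ramets, 3)
  expect_equal(g$calls[ramets[1], ], g$calls[ramets[2], ])
  k <- estimate_kinship(g)
  expect_equal(unname(k[ramets[1], ramets[3]]), 0.5, tolerance = 1e-12)
})

test_that("zero differentiation leaves only sampling noise between sites", {
  spec <- synthetic_spec(n_loci = 2000, site_sizes = c(A = 50, B = 50),
                         fst = 0)
  out <- generate_synthetic(spec, seed = 602)
  g <- out$genotypes
  sm <- g$sample_meta
  fA <- allele_freqs(g, sm$sample_id[sm$site == "A"])
  fB <- allele_freqs(g, sm$sample_id[sm$site == "B"])
  p <- (fA + fB) / 2
  # E[(fA - fB)^2] under pure binomial sampling = p(1-p) (1/2nA + 1/2nB)
  obs <- mean((fA - fB)^2)
  exp_noise <- mean(p * (1 - p)) * (1 / 100 + 1 / 100)
  expect_lt(abs(obs - exp_noise) / exp_noise, 0.15)
})

test_that("differentiated sites separate more than sampling noise predicts", {
  spec <- synthetic_spec(n_loci = 1000, site_sizes = c(A = 50, B = 50),
                         fst = 0.15)
  out <- generate_synthetic(spec, seed = 603)
  g <- out$genotypes
  sm <- g$sample_meta
  fA <- allele_freqs(g, sm$sample_id[sm$site == "A"])
  fB <- allele_freqs(g, sm$sample_id[sm$site == "B"])
  p <- (fA + fB) / 2
  obs <- mean((fA - fB)^2)
  exp_noise <- mean(p * (1 - p)) * (1 / 100 + 1 / 100)
  expect_gt(obs, 3 * exp_noise)
})

test_that("family structure produces elevated kinship among sibs", {
  spec <- synthetic_spec(n_loci = 800, site_sizes = c(focal = 20),
                         n_families = 2, family_size = 4)
  out <- generate_synthetic(spec, seed = 604)
  g <- out$genotypes
  k <- estimate_kinship(g)
  fam <- out$truth$families
  sibs <- fam$sample_id[fam$family == "F01"]
  within <- unclass(k)[sibs, sibs][upper.tri(diag(4))]
  expect_equal(mean(within), 0.25, tolerance = 0.05)
})

test_that("presets are reproducible and carry consistent metadata", {
  a <- condemned_scenario("pimelea_like", seed = 605)
  b <- condemned_scenario("pimelea_like", seed = 605)
  expect_identical(a$genotypes$calls, b$genotypes$calls)
  expect_identical(a$truth, b$truth)
  sm <- a$genotypes$sample_meta
  expect_equal(sum(sm$is_local), 112)  # 100 genets + 12 redundant ramets
  expect_equal(length(a$truth$clone_groups), 7)
  expect_equal(sum(lengths(a$truth$clone_groups) - 1), 12)
})

test_that("the seedling capture ceiling is planted at the configured rate", {
  out <- condemned_scenario("eucalyptus_like", seed = 606)
  g <- out$genotypes
  sm <- g$sample_meta
  adults <- sm$sample_id[sm$cohort == "adult"]
  seedl <- sm$sample_id[sm$cohort == "seedling" & sm$is_local & !sm$is_hybrid]
  expect_length(adults, 18)
  expect_length(seedl, 59 + 0)  # hybrids excluded
  ref <- common_loci(g, reference = adults, maf_min = 0.03)
  cap <- capture_proportion(g, seedl, ref)
  expect_lt(cap$proportion, 1)
  # dropped loci are a subset of the uncaptured reference loci, roughly 5%
  dropped <- intersect(out$truth$dropped_loci, ref)
  expect_gt(length(dropped) / length(ref), 0.02)
  expect_lt(length(dropped) / length(ref), 0.09)
  x <- g$calls[seedl, dropped, drop = FALSE]
  maf_seedl <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j][!is.na(x[, j])]
    p <- sum(v) / (2 * length(v))
    min(p, 1 - p)
  }, numeric(1))
  # erased minor allele, up to rare genotyping-error flips
  expect_true(all(maf_seedl < 0.05))
})

test_that("ground truth round-trips through the report writers", {
  spec <- synthetic_spec(n_loci = 50, site_sizes = c(focal = 8, other = 4),
                         n_families = 1, family_size = 3,
                         clone_ramets = c(2L))
  out <- generate_synthetic(spec, seed = 607)
  prefix <- file.path(withr::local_tempdir(), "truth")
  paths <- write_ground_truth(out$truth, prefix)
  clones <- read.delim(paste0(prefix, "_clones.tsv"))
  expect_setequal(clones$sample_id, unlist(out$truth$clone_groups))
  fams <- read.delim(paste0(prefix, "_families.tsv"))
  expect_equal(fams$sample_id, out$truth$families$sample_id)
  sites <- read.delim(paste0(prefix, "_sites.tsv"))
  expect_equal(stats::setNames(sites$site, sites$sample_id),
               out$truth$site_of_origin)
  freqs <- read.delim(paste0(prefix, "_site_freqs.tsv"))
  expect_equal(as.matrix(freqs), out$truth$site_freqs, tolerance = 1e-12,
               ignore_attr = TRUE)
})
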