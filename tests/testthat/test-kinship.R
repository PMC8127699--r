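test_that("genetically identical samples have kinship exactly 0.5", {
  set.seed(101)
  x <- hw_matrix(6, runif(400, 0.1, 0.9))
  x <- rbind(x, dup = x[1, ])
  g <- geno_matrix(x)
  k <- estimate_kinship(g)
  expect_equal(k["s1", "dup"], 0.5, tolerance = 1e-12)
  expect_true(isSymmetric(unclass(k)))
})

test_that("kinship recovers unrelated and parent-offspring expectations", {
  set.seed(102)
  L <- 5000
  n <- 100
  p <- runif(L, 0.1, 0.9)
  X <- hw_matrix(n, p)
  # parent-offspring by Mendelian segregation from s1 x s2
  child <- rbinom(L, 1, X[1, ] / 2) + rbinom(L, 1, X[2, ] / 2)
  X <- rbind(X, child = child)
  k <- estimate_kinship(geno_matrix(X))
  unrel <- k[3:40, 3:40][upper.tri(k[3:40, 3:40])]
  expect_lt(abs(mean(unrel)), 0.02)
  expect_equal(unname(k["s1", "child"]), 0.25, tolerance = 0.03)
})

test_that("kinship is invariant to locus order and insensitive to missing-data pattern", {
  set.seed(103)
  x <- hw_matrix(12, runif(300, 0.1, 0.9))
  x[sample(length(x), 150)] <- NA
  g <- geno_matrix(x)
  k1 <- estimate_kinship(g)
  g2 <- subset_geno(g, loci = rev(locus_ids(g)))
  k2 <- estimate_kinship(g2, allele_freq = rev(allele_freqs(g)))
  expect_equal(unclass(k1), unclass(k2), tolerance = 1e-12)
})

test_that("pairs with few shared loci are flagged unreliable", {
  set.seed(104)
  x <- hw_matrix(4, runif(60, 0.2, 0.8))
  x[1, 31:60] <- NA
  x[2, 1:30] <- NA  # pair (s1, s2) shares zero loci
  expect_warning(k <- estimate_kinship(geno_matrix(x), min_shared = 50),
                 "flagged unreliable")
  expect_true(attr(k, "unreliable")["s1", "s2"])
  expect_false(attr(k, "unreliable")["s3", "s4"])
})

test_that("similar groups are single-linkage components with min-missing representatives", {
  K <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  K["A", "B"] <- K["B", "A"] <- 0.45
  K["B", "C"] <- K["C", "B"] <- 0.42
  K["A", "C"] <- K["C", "A"] <- 0.10
  diag(K) <- NA
  k <- structure(K, class = c("kinship", "matrix"))
  gr <- similar_groups(k, 0.4, n_missing = c(A = 5, B = 2, C = 9, D = 0))
  expect_length(gr, 1)
  expect_setequal(gr[[1]]$members, c("A", "B", "C"))
  expect_equal(gr[[1]]$representative, "B")

  # ties broken lexicographically
  gr2 <- similar_groups(k, 0.4, n_missing = c(A = 2, B = 2, C = 9, D = 0))
  expect_equal(gr2[[1]]$representative, "A")

  # all below threshold: empty list
  expect_length(similar_groups(k, 0.46, n_missing = c(A = 0, B = 0, C = 0, D = 0)), 0)
})

test_that("raising the threshold never merges groups", {
  set.seed(105)
  spec <- synthetic_spec(n_loci = 400, site_sizes = c(focal = 20),
                         clone_ramets = c(3L, 2L, 2L), error_rate = 0.01)
  g <- generate_synthetic(spec, seed = 7)$genotypes
  k <- estimate_kinship(g)
  for (th in c(0.3, 0.4)) {
    lo <- similar_groups(k, th, n_missing = g)
    hi <- similar_groups(k, th + 0.05, n_missing = g)
    # every high-threshold group sits inside one low-threshold group
    for (grp in hi) {
      containing <- vapply(lo, function(x) all(grp$members %in% x$members),
                           logical(1))
      expect_equal(sum(containing), 1L)
    }
  }
})

test_that("pruning keeps representatives and removes sum(size - 1) samples", {
  set.seed(106)
  spec <- synthetic_spec(n_loci = 400, site_sizes = c(focal = 20),
                         clone_ramets = c(4L, 3L, 2L), error_rate = 0.005)
  out <- generate_synthetic(spec, seed = 8)
  g <- out$genotypes
  k <- estimate_kinship(g)
  gr <- similar_groups(k, 0.4, n_missing = g)
  gp <- prune_similar(g, gr)
  sizes <- vapply(gr, function(x) length(x$members), integer(1))
  expect_length(attr(gp, "removed_samples"), sum(sizes - 1))
  # no remaining pair among former group members reaches the threshold
  kept <- intersect(unlist(lapply(gr, `[[`, "members")), sample_ids(gp))
  if (length(kept) > 1) {
    expect_true(all(unclass(k)[kept, kept][upper.tri(diag(length(kept)))] < 0.4))
  }
  # empty group list is the identity
  expect_identical(prune_similar(g, list())$calls, g$calls)
  # a one-group prune removes size - 1
  one <- list(list(members = sample_ids(g)[1:3],
                   representative = sample_ids(g)[1]))
  expect_equal(nrow(prune_similar(g, one)$calls), nrow(g$calls) - 2)
  # unknown representative is a hard error
  bad <- list(list(members = c("nope", sample_ids(g)[1]),
                   representative = "nope"))
  expect_error(prune_similar(g, bad), "not in matrix")
})

test_that("kinship histogram counts all unordered pairs", {
  set.seed(107)
  k <- toy_kinship(3)
  h <- kinship_histogram(k, bins = 5)
  expect_equal(sum(h$count), 3L)
  # all values in one bin
  K <- matrix(0.2, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(K) <- NA
  h2 <- kinship_histogram(structure(K, class = c("kinship", "matrix")),
                          bins = c(0, 0.1, 0.25, 0.5))
  expect_equal(h2$count, c(0L, 3L, 0L))
  # recount on a random matrix
  k3 <- toy_kinship(10)
  h3 <- kinship_histogram(k3, bins = 10)
  expect_equal(sum(h3$count), choose(10, 2))
})
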