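# Fixture builders and independent oracles shared across the test files.

# Hardy-Weinberg dosage matrix with given allele frequencies
hw_matrix <- function(n, p, ids = paste0("s", seq_len(n))) {
  m <- matrix(stats::rbinom(n * length(p), 2L, rep(p, each = n)),
              n, length(p), dimnames = list(ids, paste0("L", seq_along(p))))
  m
}

hw_geno <- function(n, p, ...) geno_matrix(hw_matrix(n, p, ...))

# independent oracle: mean expected heterozygosity of a complete matrix
he_oracle <- function(X) {
  p <- colMeans(X) / 2
  mean(2 * p * (1 - p))
}

# independent oracle: capture = both alleles present, explicit per-locus loop
capture_oracle <- function(X) {
  cap <- vapply(seq_len(ncol(X)), function(j) {
    v <- X[, j][!is.na(X[, j])]
    any(v > 0) && any(v < 2)
  }, logical(1))
  mean(cap)
}

# symmetric ad hoc kinship matrix for spatial tests
toy_kinship <- function(n, lo = -0.05, hi = 0.45, ids = paste0("p", seq_len(n))) {
  K <- matrix(stats::runif(n * n, lo, hi), n, n)
  K <- (K + t(K)) / 2
  diag(K) <- NA_real_
  dimnames(K) <- list(ids, ids)
  structure(K, class = c("kinship", "matrix"))
}

# all permutations of 1..n as a matrix (rows), iterative insertion
all_perms <- function(n) {
  P <- matrix(1L, 1, 1)
  for (k in 2:n) {
    m <- nrow(P)
    out <- matrix(0L, m * k, k)
    for (pos in seq_len(k)) {
      left <- P[, seq_len(pos - 1), drop = FALSE]
      right <- if (pos <= k - 1) P[, pos:(k - 1), drop = FALSE] else
        P[, 0, drop = FALSE]
      out[((pos - 1) * m + 1):(pos * m), ] <- cbind(left, k, right)
    }
    P <- out
  }
  P
}

# quick cooling schedule for smoke tests where optimality is not asserted
fast_cooling <- function() sa_cooling(swaps_per_temp = 20, max_temps = 30,
                                      max_rejects = 200)

# standard pimelea-like preparation chain used by several files
prepare_pimelea <- function(seed = 42) {
  sim <- condemned_scenario("pimelea_like", seed = seed)
  g <- remove_high_missing_samples(filter_loci(sim$genotypes))
  k <- estimate_kinship(g)
  groups <- similar_groups(k, 0.4, n_missing = g)
  gp <- prune_similar(g, groups)
  local <- gp$sample_meta$sample_id[gp$sample_meta$is_local]
  gl <- filter_loci(subset_geno(gp, samples = local),
                    reproducibility_min = NULL, missing_max = NULL,
                    require_complete = TRUE)
  ref <- common_loci(gl, maf_min = 0.02)
  list(sim = sim, kinship = k, groups = groups, pruned = gp,
       condemned = subset_geno(gl, loci = ref), reference = ref)
}
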