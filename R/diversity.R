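#' Gene diversity (expected heterozygosity)
#'
#' Mean over loci of `2 p (1 - p)` with `p` the alternate-allele frequency
#' computed on the subset (Nei's gene diversity). No sample-size correction
#' is applied: the value is used as an objective that ranks subsets of a
#' fixed size, where the `2n/(2n - 1)` factor is constant and cannot change
#' the ranking. Reported absolute values follow the same convention.
#'
#' @param g A `geno` object.
#' @param samples Sample ids of the subset (default: all samples).
#' @return Mean expected heterozygosity (scalar in \[0, 0.5\] for biallelic
#'   loci).
#' @export
gene_diversity <- function(g, samples = NULL) {
  p <- allele_freqs(g, samples)
  mean(2 * p * (1 - p), na.rm = TRUE)
}

#' Allele capture against a common-locus reference set
#'
#' A reference locus is "captured" by a subset when both of its alleles
#' occur in the subset, i.e. at least one call with dosage greater than 0
#' and at least one with dosage less than 2 (missing calls ignored). The
#' reference set is typically [common_loci()] of the condemned population.
#'
#' @param g A `geno` object.
#' @param samples Subset of sample ids.
#' @param reference_common Character vector of reference locus ids.
#' @return List of class `capture_result` with `samples`,
#'   `n_reference_loci`, `n_captured`, `proportion`.
#' @export
capture_proportion <- function(g, samples, reference_common) {
  stopifnot(inherits(g, "geno"), length(samples) > 0)
  missing_l <- setdiff(reference_common, locus_ids(g))
  if (length(missing_l))
    stop("reference loci absent from matrix: ",
         paste(utils::head(missing_l, 5), collapse = ", "))
  x <- g$calls[samples, reference_common, drop = FALSE]
  has_alt <- colSums(x > 0, na.rm = TRUE) > 0
  has_ref <- colSums(x < 2, na.rm = TRUE) > 0
  captured <- has_alt & has_ref
  structure(list(samples = samples,
                 n_reference_loci = length(reference_common),
                 n_captured = sum(captured),
                 proportion = sum(captured) / length(reference_common)),
            class = "capture_result")
}

#' @export
print.capture_result <- function(x, ...) {
  cat(sprintf("capture: %d/%d reference loci polymorphic (%.1f%%) in %d samples\n",
              x$n_captured, x$n_reference_loci, 100 * x$proportion,
              length(x$samples)))
  invisible(x)
}

#' Random-subset baseline for capture and diversity
#'
#' Draws `n_reps` subsets of size `n_select` uniformly without replacement
#' and reports per-replicate capture proportion and gene diversity plus
#' their means and standard deviations. This is the "random" arm that
#' optimized propagation populations are compared against.
#'
#' @param g A `geno` object.
#' @param n_select Subset size.
#' @param reference_common Reference locus ids for capture.
#' @param n_reps Number of replicates (default 100).
#' @param candidates Pool to draw from (default: all samples).
#' @param seed Optional integer seed for reproducibility.
#' @return List with `proportions`, `gene_diversity` (per replicate),
#'   `mean_proportion`, `sd_proportion`, `mean_gene_diversity`.
#' @export
random_baseline <- function(g, n_select, reference_common, n_reps = 100,
                            candidates = NULL, seed = NULL) {
  stopifnot(inherits(g, "geno"))
  if (is.null(candidates)) candidates <- sample_ids(g)
  stopifnot(n_select <= length(candidates))
  if (!is.null(seed)) set.seed(seed)
  props <- numeric(n_reps)
  hes <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    sel <- sample(candidates, n_select)
    props[r] <- capture_proportion(g, sel, reference_common)$proportion
    hes[r] <- gene_diversity(g, sel)
  }
  list(proportions = props, gene_diversity = hes,
       mean_proportion = mean(props), sd_proportion = stats::sd(props),
       mean_gene_diversity = mean(hes))
}

#' Inbreeding coefficient and allelic richness
#'
#' Multilocus `F_IS` is computed as a ratio of averages over polymorphic
#' loci: `1 - mean(Ho) / mean(He)`, with the unbiased expected
#' heterozygosity `He = 2 p q * 2n / (2n - 1)` (per-locus sample size `n`).
#' Allelic richness is the mean number of distinct alleles per locus
#' (1 for monomorphic, 2 for polymorphic loci in biallelic data), with
#' optional rarefaction to a fixed number of genes.
#'
#' @param g A `geno` object.
#' @param samples Subset of sample ids (default: all).
#' @param rarefy Optional number of *diploid individuals* to rarefy
#'   richness to; default `NULL` (no rarefaction).
#' @return List of class `diversity_summary` with `gene_diversity`
#'   (uncorrected, as in [gene_diversity()]), `allelic_richness`, `f_is`,
#'   `n_polymorphic`. When every locus is monomorphic, `f_is` is `NA` with
#'   a warning.
#' @export
fis_and_richness <- function(g, samples = NULL, rarefy = NULL) {
  stopifnot(inherits(g, "geno"))
  if (is.null(samples)) samples <- sample_ids(g)
  x <- g$calls[samples, , drop = FALSE]
  n_called <- colSums(!is.na(x))
  ok <- n_called > 0
  x <- x[, ok, drop = FALSE]
  n_called <- n_called[ok]
  p <- colSums(x, na.rm = TRUE) / (2 * n_called)
  poly <- p > 0 & p < 1

  # allelic richness
  if (is.null(rarefy)) {
    richness <- mean(1 + poly)
  } else {
    k <- 2 * rarefy  # genes
    n_genes <- 2 * n_called
    c_alt <- round(p * n_genes)
    c_ref <- n_genes - c_alt
    pres <- function(c_a) {
      # P(allele with c_a copies appears in a sample of k genes)
      ifelse(n_genes - c_a < k, 1,
             1 - exp(lchoose(n_genes - c_a, k) - lchoose(n_genes, k)))
    }
    if (any(n_genes < k))
      warning("some loci have fewer genes than the rarefaction size; ",
              "using observed richness there")
    richness <- mean(pres(c_alt) + pres(c_ref))
  }

  if (!any(poly)) {
    warning("all loci monomorphic; F_IS undefined")
    f_is <- NA_real_
  } else {
    xp <- x[, poly, drop = FALSE]
    np <- n_called[poly]
    pp <- p[poly]
    ho <- colSums(xp == 1, na.rm = TRUE) / np
    he <- 2 * pp * (1 - pp) * (2 * np) / (2 * np - 1)
    f_is <- 1 - mean(ho) / mean(he)
  }
  structure(list(gene_diversity = mean(2 * p * (1 - p)),
                 allelic_richness = richness,
                 f_is = f_is,
                 n_polymorphic = sum(poly)),
            class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf("He = %.4f, allelic richness = %.3f, F_IS = %s (%d polymorphic loci)\n",
              x$gene_diversity, x$allelic_richness,
              ifelse(is.na(x$f_is), "NA", sprintf("%.3f", x$f_is)),
              x$n_polymorphic))
  invisible(x)
}

#' Write diversity/capture metrics to a tab-separated report
#' @param rows Data frame of metrics (one row per subset/label).
#' @param path Output path.
#' @export
write_metrics <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
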