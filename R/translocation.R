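#' Translocation design: equal ramets per genet
#'
#' A translocation population of `n_total` plants is assembled from
#' `length(genets)` propagation-population genets by taking the same number
#' of vegetative cuttings (ramets) from each; e.g. 256 plants from 32
#' genets means 8 ramets each. `n_total` must be divisible by the number
#' of genets.
#'
#' @param genets Character vector of genet (sample) ids, typically the
#'   `selected` set of a `subset_design`.
#' @param n_total Translocation population size `N_T`, or `NULL` to give
#'   `ramets_per_genet` directly.
#' @param ramets_per_genet Ramets per genet (used when `n_total` is
#'   `NULL`).
#' @return A `translocation_design`: list with `genets`,
#'   `ramets_per_genet`, `n_total`.
#' @export
translocation_design <- function(genets, n_total = NULL,
                                 ramets_per_genet = NULL) {
  np <- length(genets)
  stopifnot(np >= 1)
  if (is.null(ramets_per_genet)) {
    stopifnot(!is.null(n_total))
    if (n_total %% np != 0)
      stop(sprintf("N_T = %d is not divisible by N_P = %d", n_total, np))
    ramets_per_genet <- n_total %/% np
  }
  stopifnot(ramets_per_genet >= 1)
  structure(list(genets = genets, ramets_per_genet = ramets_per_genet,
                 n_total = np * ramets_per_genet),
            class = "translocation_design")
}

#' Founding genotypes of a translocation population
#'
#' Each founder is an exact genotype copy of its genet: clonal propagation
#' introduces no mutation, so founder allele frequencies equal the
#' genet-set frequencies and no allele absent from the genets can ever
#' appear downstream.
#'
#' @param g A `geno` object with complete calls at the loci of interest.
#' @param design A [translocation_design()].
#' @param loci Optional locus ids to restrict to (default: all loci in
#'   `g`).
#' @return Integer dosage matrix, founders x loci; row names are
#'   `<genet>.<ramet>`.
#' @export
found_population <- function(g, design, loci = NULL) {
  stopifnot(inherits(g, "geno"), inherits(design, "translocation_design"))
  missing_g <- setdiff(design$genets, sample_ids(g))
  if (length(missing_g))
    stop("genets absent from matrix: ", paste(missing_g, collapse = ", "))
  if (is.null(loci)) loci <- locus_ids(g)
  X <- g$calls[design$genets, loci, drop = FALSE]
  if (anyNA(X)) stop("founder loci must be complete (no missing calls)")
  idx <- rep(seq_along(design$genets), each = design$ramets_per_genet)
  founders <- X[idx, , drop = FALSE]
  rownames(founders) <- paste0(design$genets[idx], ".",
                               sequence(rep(design$ramets_per_genet,
                                            length(design$genets))))
  founders
}

# one Wright-Fisher generation: constant size, random parent pairs,
# fair Mendelian segregation, unlinked loci
.wf_generation <- function(X, selfing_rate = 0) {
  n <- nrow(X)
  L <- ncol(X)
  p1 <- sample.int(n, n, replace = TRUE)
  p2 <- sample.int(n, n, replace = TRUE)
  if (selfing_rate > 0) {
    self <- stats::runif(n) < selfing_rate
    p2[self] <- p1[self]
  }
  # each parent transmits one allele per locus: P(alt) = dosage / 2
  g1 <- stats::rbinom(n * L, 1L, X[p1, , drop = FALSE] / 2)
  g2 <- stats::rbinom(n * L, 1L, X[p2, , drop = FALSE] / 2)
  matrix(g1 + g2, n, L)
}

#' Forward simulation of allele retention in a translocation population
#'
#' Simulates a neutral discrete Wright-Fisher population of constant size
#' (the number of founders): in each of `generations` non-overlapping
#' generations, every offspring draws two parents uniformly at random with
#' replacement (forced self-fertilization with probability `selfing_rate`;
#' otherwise two independent draws that may still coincide by chance), and
#' each parent contributes one allele per locus by fair Mendelian
#' segregation, loci unlinked. After the final generation, the proportion
#' of `reference_common` loci still polymorphic is recorded.
#'
#' @param founders Integer dosage matrix (founders x loci), e.g. from
#'   [found_population()].
#' @param reference_common Locus ids (or column indices) of the
#'   common-locus reference set; default: all columns.
#' @param generations Number of generations (default 10).
#' @param selfing_rate Probability of forced selfing per offspring
#'   (default 0).
#' @param n_replicates Independent replicate simulations (default 100).
#' @param seed Optional integer seed.
#' @param track_he If `TRUE`, also record mean expected heterozygosity of
#'   the reference loci at each generation (replicates x generations + 1
#'   matrix, column 1 = founders).
#' @return A `retention_result`: list with `proportions` (per replicate),
#'   `mean`, `q025`, `q975`, `n_reference_loci`, and `he_trajectory` when
#'   tracked.
#' @export
simulate_translocation <- function(founders, reference_common = NULL,
                                   generations = 10, selfing_rate = 0,
                                   n_replicates = 100, seed = NULL,
                                   track_he = FALSE) {
  stopifnot(nrow(founders) >= 2, generations >= 1,
            selfing_rate >= 0, selfing_rate <= 1)
  if (is.null(reference_common)) reference_common <- colnames(founders)
  if (is.character(reference_common)) {
    missing_l <- setdiff(reference_common, colnames(founders))
    if (length(missing_l))
      stop("reference loci absent from founders: ",
           paste(utils::head(missing_l, 5), collapse = ", "))
    ref_idx <- match(reference_common, colnames(founders))
  } else {
    ref_idx <- reference_common
  }
  if (!is.null(seed)) set.seed(seed)
  Xf <- founders[, ref_idx, drop = FALSE]
  if (anyNA(Xf)) stop("founder genotypes must be complete")
  n_ref <- ncol(Xf)
  props <- numeric(n_replicates)
  he_traj <- if (track_he)
    matrix(NA_real_, n_replicates, generations + 1) else NULL
  mean_he <- function(X) {
    p <- colMeans(X) / 2
    mean(2 * p * (1 - p))
  }
  for (r in seq_len(n_replicates)) {
    X <- Xf
    if (track_he) he_traj[r, 1] <- mean_he(X)
    for (gen in seq_len(generations)) {
      X <- .wf_generation(X, selfing_rate)
      if (track_he) he_traj[r, gen + 1] <- mean_he(X)
    }
    cs <- colSums(X)
    props[r] <- sum(cs > 0 & cs < 2 * nrow(X)) / n_ref
  }
  structure(list(proportions = props, mean = mean(props),
                 q025 = unname(stats::quantile(props, 0.025)),
                 q975 = unname(stats::quantile(props, 0.975)),
                 n_reference_loci = n_ref,
                 generations = generations,
                 n_founders = nrow(founders),
                 he_trajectory = he_traj),
            class = "retention_result")
}

#' @export
print.retention_result <- function(x, ...) {
  cat(sprintf(
    "<retention> N_T = %d, %d generations: mean %.3f [%.3f, %.3f] of %d loci polymorphic (%d reps)\n",
    x$n_founders, x$generations, x$mean, x$q025, x$q975,
    x$n_reference_loci, length(x$proportions)))
  invisible(x)
}

#' Factorial grid of translocation designs
#'
#' Full factorial over propagation designs and translocation sizes: for
#' every (N_P design, N_T) pair where N_T is divisible by N_P, founds a
#' population with equal ramets per genet and simulates retention.
#' Indivisible pairs are skipped with a warning.
#'
#' @param g A `geno` object (complete at `reference_common`).
#' @param propagation_designs Named list of genet-id vectors (or
#'   `subset_design` objects); names report N_P.
#' @param NT_values Vector of translocation sizes, e.g.
#'   `c(64, 128, 192, 256, 320)`.
#' @param reference_common Reference locus ids.
#' @param ... Passed to [simulate_translocation()] (`generations`,
#'   `selfing_rate`, `n_replicates`).
#' @param seed Optional integer seed; per-cell sub-seeds are derived from
#'   it so the grid is reproducible.
#' @return Data frame with one row per simulated cell: `n_p`, `n_t`,
#'   `ramets`, `founder_capture` (proportion of reference loci polymorphic
#'   among the genets), `mean_retained`, `q025`, `q975`; the per-cell
#'   `retention_result`s are attached as the `results` attribute.
#' @export
design_grid <- function(g, propagation_designs, NT_values, reference_common,
                        ..., seed = NULL) {
  stopifnot(inherits(g, "geno"))
  if (!is.null(seed)) set.seed(seed)
  cell_seeds <- sample.int(.Machine$integer.max,
                           length(propagation_designs) * length(NT_values))
  rows <- list()
  results <- list()
  cell <- 0L
  for (di in seq_along(propagation_designs)) {
    des <- propagation_designs[[di]]
    genets <- if (inherits(des, "subset_design")) des$selected else des
    np <- length(genets)
    fc <- capture_proportion(g, genets, reference_common)$proportion
    for (nt in NT_values) {
      cell <- cell + 1L
      if (nt %% np != 0) {
        warning(sprintf("skipping N_T = %d: not divisible by N_P = %d",
                        nt, np))
        next
      }
      td <- translocation_design(genets, n_total = nt)
      founders <- found_population(g, td, loci = reference_common)
      res <- simulate_translocation(founders, seed = cell_seeds[cell], ...)
      rows[[length(rows) + 1]] <- data.frame(
        n_p = np, n_t = nt, ramets = td$ramets_per_genet,
        founder_capture = fc, mean_retained = res$mean,
        q025 = res$q025, q975 = res$q975)
      results[[sprintf("np%d_nt%d", np, nt)]] <- res
    }
  }
  if (length(rows) == 0) return(NULL)
  out <- do.call(rbind, rows)
  attr(out, "results") <- results
  out
}

#' Write grid retention results as tab-separated text
#' @param grid Output of [design_grid()].
#' @param path Output path.
#' @param per_replicate If `TRUE`, write one row per replicate instead of
#'   the summary.
#' @export
write_grid <- function(grid, path, per_replicate = FALSE) {
  if (per_replicate) {
    results <- attr(grid, "results")
    rows <- do.call(rbind, lapply(names(results), function(nm) {
      res <- results[[nm]]
      np_nt <- as.integer(strsplit(gsub("np|nt", "", nm), "_")[[1]])
      data.frame(n_p = np_nt[1], n_t = np_nt[2],
                 replicate = seq_along(res$proportions),
                 proportion_retained = res$proportions)
    }))
    utils::write.table(rows, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  } else {
    utils::write.table(as.data.frame(grid), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
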