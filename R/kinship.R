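#' Pairwise kinship by the PLINK method of moments
#'
#' Estimates, for every pair of samples, the probabilities `k0`, `k1`, `k2`
#' of sharing 0, 1 or 2 alleles identical by descent, from the observed
#' identity-by-state (IBS) counts and sample allele frequencies, and
#' returns kinship `= 0.5 * (k2 + 0.5 * k1)`. Only loci with non-missing
#' calls in both members of a pair contribute. Genetically identical
#' individuals (e.g. ramets of one genet, genotyped without error) have
#' kinship exactly 0.5; unrelated outbred individuals are near 0.
#'
#' The method-of-moments system uses the per-locus conditional IBS
#' probabilities given IBD state (with `p` the alternate-allele frequency
#' and `q = 1 - p`): `P(IBS0|IBD0) = 2 p^2 q^2`,
#' `P(IBS1|IBD0) = 4 p^3 q + 4 p q^3`, `P(IBS1|IBD1) = 2 p q`. `k0` and
#' `k1` are solved from the IBS0 and IBS1 counts, and `k2 = 1 - k0 - k1`.
#' With `bound = TRUE` (default) the `(k0, k1, k2)` estimate is clamped to
#' the probability simplex before kinship is computed, the standard PLINK
#' bounding; with `bound = FALSE` raw estimates are used and kinship can
#' fall slightly outside `[0, 0.5]` by sampling noise.
#'
#' @param g A `geno` object with at least two samples.
#' @param allele_freq Optional numeric vector of per-locus alternate-allele
#'   frequencies to use for the expectations; default: estimated from all
#'   samples in `g`.
#' @param min_shared Pairs sharing fewer than this many non-missing loci are
#'   flagged unreliable (default 50).
#' @param bound Clamp the IBD-state estimates to the simplex (default TRUE).
#' @return A `kinship` object: the symmetric kinship matrix with attributes
#'   `n_shared` (pairwise complete-locus counts) and `unreliable` (logical
#'   matrix). The diagonal is set to `NA`; no downstream operation uses it.
#' @export
estimate_kinship <- function(g, allele_freq = NULL, min_shared = 50,
                             bound = TRUE) {
  stopifnot(inherits(g, "geno"))
  x <- g$calls
  n <- nrow(x)
  if (n < 2) stop("need at least two samples")
  if (is.null(allele_freq)) allele_freq <- allele_freqs(g)
  p <- as.numeric(allele_freq)
  if (length(p) != ncol(x)) stop("allele_freq length != number of loci")
  p[is.na(p)] <- 0  # loci with no data contribute nothing below
  q <- 1 - p

  V <- (!is.na(x)) * 1           # validity indicator
  A0 <- (!is.na(x) & x == 0) * 1 # per-dosage indicators
  A1 <- (!is.na(x) & x == 1) * 1
  A2 <- (!is.na(x) & x == 2) * 1

  # observed IBS counts over pairwise-complete loci
  N0 <- A0 %*% t(A2); N0 <- N0 + t(N0)
  N2 <- A0 %*% t(A0) + A1 %*% t(A1) + A2 %*% t(A2)
  Ntot <- V %*% t(V)
  N1 <- Ntot - N0 - N2

  # expected per-locus IBS-class probabilities, summed over shared loci
  a00 <- 2 * p^2 * q^2
  a10 <- 4 * p^3 * q + 4 * p * q^3
  a11 <- 2 * p * q
  E00 <- V %*% (a00 * t(V))
  E10 <- V %*% (a10 * t(V))
  E11 <- V %*% (a11 * t(V))

  k0 <- N0 / E00
  k1 <- (N1 - k0 * E10) / E11
  if (bound) {
    k0 <- pmin(pmax(k0, 0), 1)
    k1 <- pmin(pmax(k1, 0), 1 - k0)
  }
  k2 <- 1 - k0 - k1
  kin <- 0.5 * (k2 + 0.5 * k1)

  dimnames(kin) <- list(rownames(x), rownames(x))
  diag(kin) <- NA_real_
  kin <- (kin + t(kin)) / 2  # enforce exact symmetry
  unreliable <- Ntot < min_shared
  diag(unreliable) <- FALSE
  if (any(unreliable))
    warning(sum(unreliable[upper.tri(unreliable)]),
            " pair(s) share fewer than ", min_shared,
            " loci; estimates flagged unreliable")
  structure(kin, n_shared = Ntot, unreliable = unreliable,
            class = c("kinship", "matrix"))
}

#' @export
print.kinship <- function(x, ...) {
  v <- x[upper.tri(x)]
  cat(sprintf("<kinship> %d samples, %d pairs; range %.3f..%.3f\n",
              nrow(x), length(v), min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  invisible(x)
}

#' Groups of highly similar individuals
#'
#' Builds a graph with an edge between every pair whose kinship is at least
#' `threshold` and returns its connected components of size two or more
#' (single linkage). Each group gets a representative: the member with the
#' fewest missing genotype calls, ties broken lexicographically by id.
#'
#' @param k A `kinship` object (or symmetric matrix with dimnames).
#' @param threshold Kinship threshold in (0, 0.5], e.g. 0.4 or 0.45
#'   depending on how genotyping error depresses clone kinship in the data
#'   at hand (inspect [kinship_histogram()]).
#' @param n_missing Named integer vector of missing-call counts per sample,
#'   or a `geno` object to take them from. Required to pick representatives;
#'   if omitted, ties are broken lexicographically only.
#' @return List of groups, each a list with `members` (character),
#'   `representative` (single id); empty list when no pair reaches the
#'   threshold.
#' @export
similar_groups <- function(k, threshold, n_missing = NULL) {
  stopifnot(threshold > 0, threshold <= 0.5)
  if (inherits(n_missing, "geno"))
    n_missing <- stats::setNames(n_missing$sample_meta$n_missing,
                                 n_missing$sample_meta$sample_id)
  km <- unclass(k)
  ids <- rownames(km)
  adj <- !is.na(km) & km >= threshold
  diag(adj) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gr)
  out <- list()
  for (ci in seq_len(comp$no)) {
    members <- sort(ids[comp$membership == ci])
    if (length(members) < 2) next
    if (!is.null(n_missing)) {
      nm <- n_missing[members]
      if (any(is.na(nm)))
        stop("n_missing not available for: ",
             paste(members[is.na(nm)], collapse = ", "))
      members_by <- members[order(nm, members)]
    } else {
      members_by <- members
    }
    out[[length(out) + 1]] <- list(members = members,
                                   representative = members_by[1])
  }
  out
}

#' Prune similar groups to one representative each
#'
#' @param g A `geno` object.
#' @param groups Output of [similar_groups()]; groups must be disjoint.
#' @return A `geno` object with all non-representative group members
#'   removed; the `removed_samples` attribute lists them.
#' @export
prune_similar <- function(g, groups) {
  stopifnot(inherits(g, "geno"))
  if (length(groups) == 0) return(g)
  all_members <- unlist(lapply(groups, `[[`, "members"))
  if (anyDuplicated(all_members)) stop("groups are not disjoint")
  reps <- vapply(groups, `[[`, character(1), "representative")
  missing_rep <- setdiff(reps, sample_ids(g))
  if (length(missing_rep))
    stop("representative(s) not in matrix: ",
         paste(missing_rep, collapse = ", "))
  drop <- setdiff(all_members, reps)
  out <- subset_geno(g, samples = setdiff(sample_ids(g), drop))
  attr(out, "removed_samples") <- drop
  out
}

#' Histogram of pairwise kinship values
#'
#' Counts all unordered pairs; used to choose a species-specific clone
#' threshold by inspecting where the near-0.5 clone mode separates from
#' the close-relative background.
#'
#' @param k A `kinship` object.
#' @param bins Number of bins, or a vector of breakpoints passed to
#'   [hist()].
#' @return Data frame with columns `lower`, `upper`, `count`.
#' @export
kinship_histogram <- function(k, bins = 50) {
  v <- unclass(k)[upper.tri(k)]
  v <- v[!is.na(v)]
  h <- graphics::hist(v, breaks = bins, plot = FALSE)
  data.frame(lower = utils::head(h$breaks, -1),
             upper = utils::tail(h$breaks, -1),
             count = h$counts)
}

#' Write a kinship matrix (square, tab-separated, header ids)
#' @param k A `kinship` object.
#' @param path Output path.
#' @export
write_kinship <- function(k, path) {
  m <- as.data.frame(unclass(k))
  utils::write.table(data.frame(sample_id = rownames(m), m,
                                check.names = FALSE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write similar-group membership as tab-separated text
#' @param groups Output of [similar_groups()].
#' @param n_missing Optional named vector of per-sample missing counts.
#' @param path Output path.
#' @export
write_groups <- function(groups, path, n_missing = NULL) {
  rows <- do.call(rbind, lapply(seq_along(groups), function(i) {
    gr <- groups[[i]]
    data.frame(group_id = i, member = gr$members,
               representative_flag = as.integer(gr$members == gr$representative),
               n_missing = if (is.null(n_missing)) NA_integer_
                           else as.integer(n_missing[gr$members]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(group_id = integer(0), member = character(0),
                       representative_flag = integer(0),
                       n_missing = integer(0))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
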