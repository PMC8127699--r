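#' Specification for a synthetic SNP dataset
#'
#' Describes a multi-site sampling design with planted structure at every
#' level the analysis workflow operates on: site differentiation (ancestral
#' allele frequencies are beta-distributed and per-site frequencies follow
#' a Balding-Nichols model with the given F_ST), full-sib families within
#' the focal site, clonal genets observed as multiple ramets with
#' per-call genotyping error, uniform missingness, and a reproducibility
#' score distribution in which a configurable fraction of loci falls below
#' the usual 0.96 quality threshold.
#'
#' @param n_loci Number of biallelic loci.
#' @param site_sizes Named integer vector: genets per site; the first site
#'   is the focal (condemned) population.
#' @param fst Balding-Nichols differentiation parameter in \[0, 1).
#' @param n_families Full-sib families within the focal site.
#' @param family_size Offspring per family (these genets replace unrelated
#'   ones; `n_families * family_size` must not exceed the focal site size).
#' @param clone_ramets Integer vector: number of ramets observed for each
#'   clonal genet in the focal site (e.g. `c(4, 4, 3, 2, 2, 2, 2)` plants
#'   7 clone groups and 12 redundant samples). Ramets are extra samples.
#' @param error_rate Per-call probability of a single-step dosage error
#'   (0 to 1 or 1 to 0/2 etc.).
#' @param missing_rate Per-call probability of a missing genotype.
#' @param low_repro_frac Fraction of loci given reproducibility scores
#'   below 0.96.
#' @param beta_shape Shape parameters of the (symmetric) beta distribution
#'   of ancestral frequencies, truncated to \[0.02, 0.98\].
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_loci = 1000,
                           site_sizes = c(focal = 60, siteB = 20, siteC = 20),
                           fst = 0.1, n_families = 0, family_size = 4,
                           clone_ramets = integer(0), error_rate = 0,
                           missing_rate = 0, low_repro_frac = 0.1,
                           beta_shape = 0.5) {
  stopifnot(n_loci >= 1, all(site_sizes >= 1), fst >= 0, fst < 1,
            error_rate >= 0, error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1,
            low_repro_frac >= 0, low_repro_frac <= 1,
            n_families * family_size <= site_sizes[1])
  if (is.null(names(site_sizes)))
    names(site_sizes) <- paste0("site", seq_along(site_sizes))
  structure(list(n_loci = n_loci, site_sizes = site_sizes, fst = fst,
                 n_families = n_families, family_size = family_size,
                 clone_ramets = as.integer(clone_ramets),
                 error_rate = error_rate, missing_rate = missing_rate,
                 low_repro_frac = low_repro_frac, beta_shape = beta_shape),
            class = "synthetic_spec")
}

# Hardy-Weinberg genotypes: n individuals x length(p) loci
.hw_draw <- function(n, p) {
  matrix(stats::rbinom(n * length(p), 2L, rep(p, each = n)), n, length(p))
}

# Mendelian offspring of two parent dosage vectors
.mendel_child <- function(pa, pb) {
  stats::rbinom(length(pa), 1L, pa / 2) + stats::rbinom(length(pb), 1L, pb / 2)
}

# single-step dosage perturbation: 0->1, 2->1, 1 -> 0 or 2
.apply_error <- function(x, rate) {
  if (rate <= 0) return(x)
  hit <- which(stats::runif(length(x)) < rate & !is.na(x))
  v <- x[hit]
  v[v == 0] <- 1L
  v[v == 2] <- 1L
  het <- x[hit] == 1
  v[het] <- 2L * stats::rbinom(sum(het), 1L, 0.5)
  x[hit] <- v
  x
}

#' Generate a synthetic genotype dataset with planted ground truth
#'
#' Unrelated individuals are drawn at Hardy-Weinberg equilibrium from
#' their site's allele frequencies; family offspring arise by Mendelian
#' segregation from two site-drawn parents; ramets are copies of their
#' genet; genotyping error (independent single-step dosage flips) and
#' uniform missingness are applied to all emitted calls.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Optional integer seed; fixed seed gives byte-identical
#'   output.
#' @return List with `genotypes` (a `geno` object) and `truth`: a list
#'   with `clone_groups` (list of ramet-id vectors per genet),
#'   `families` (data frame sample/family), `site_of_origin`,
#'   `site_freqs` (loci x sites matrix), `ancestral_freqs`.
#' @export
generate_synthetic <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(seed)) set.seed(seed)
  L <- spec$n_loci
  # ancestral and per-site frequencies (Balding-Nichols)
  p0 <- stats::rbeta(L, spec$beta_shape, spec$beta_shape)
  p0 <- pmin(pmax(p0, 0.02), 0.98)
  n_sites <- length(spec$site_sizes)
  site_names <- names(spec$site_sizes)
  P <- matrix(NA_real_, L, n_sites, dimnames = list(NULL, site_names))
  for (s in seq_len(n_sites)) {
    P[, s] <- if (spec$fst == 0) p0 else
      stats::rbeta(L, p0 * (1 - spec$fst) / spec$fst,
                   (1 - p0) * (1 - spec$fst) / spec$fst)
  }

  calls <- NULL
  ids <- character(0)
  site_of <- character(0)
  fam_rows <- list()
  add <- function(x, id, site) {
    calls <<- rbind(calls, x)
    ids <<- c(ids, id)
    site_of <<- c(site_of, site)
  }

  focal <- site_names[1]
  pf <- P[, 1]
  n_focal <- spec$site_sizes[1]
  n_fam_members <- spec$n_families * spec$family_size
  n_unrelated <- n_focal - n_fam_members

  # families: full sibs from two unrelated site-drawn parents
  for (f in seq_len(spec$n_families)) {
    pa <- stats::rbinom(L, 2L, pf)
    pb <- stats::rbinom(L, 2L, pf)
    for (k in seq_len(spec$family_size)) {
      id <- sprintf("%s_F%02d_%02d", focal, f, k)
      add(.mendel_child(pa, pb), id, focal)
      fam_rows[[length(fam_rows) + 1]] <-
        data.frame(sample_id = id, family = sprintf("F%02d", f))
    }
  }
  # unrelated focal genets
  for (k in seq_len(n_unrelated)) {
    add(stats::rbinom(L, 2L, pf), sprintf("%s_U%03d", focal, k), focal)
  }
  # clonal genets: each observed as several ramets (extra samples)
  clone_groups <- list()
  for (cg in seq_along(spec$clone_ramets)) {
    genotype <- stats::rbinom(L, 2L, pf)
    ramet_ids <- sprintf("%s_C%02d_r%d", focal, cg,
                         seq_len(spec$clone_ramets[cg]))
    for (id in ramet_ids) add(genotype, id, focal)
    clone_groups[[sprintf("C%02d", cg)]] <- ramet_ids
  }
  # other sites: unrelated HW individuals
  for (s in seq_len(n_sites)[-1]) {
    for (k in seq_len(spec$site_sizes[s])) {
      add(stats::rbinom(L, 2L, P[, s]),
          sprintf("%s_U%03d", site_names[s], k), site_names[s])
    }
  }

  calls <- .apply_error(calls, spec$error_rate)
  if (spec$missing_rate > 0)
    calls[stats::runif(length(calls)) < spec$missing_rate] <- NA_integer_
  locus_ids <- sprintf("L%05d", seq_len(L))
  dimnames(calls) <- list(ids, locus_ids)

  # reproducibility: a low-scoring fraction below the 0.96 threshold
  low <- stats::runif(L) < spec$low_repro_frac
  repro <- ifelse(low, stats::runif(L, 0.80, 0.96),
                  stats::runif(L, 0.961, 1.0))
  lm <- data.frame(locus_id = locus_ids, reproducibility = repro)
  sm <- data.frame(sample_id = ids, site = site_of,
                   cohort = "adult", is_local = site_of == focal,
                   is_hybrid = FALSE, stringsAsFactors = FALSE)
  g <- geno_matrix(calls, locus_meta = lm, sample_meta = sm)
  truth <- list(clone_groups = clone_groups,
                families = if (length(fam_rows)) do.call(rbind, fam_rows)
                           else data.frame(sample_id = character(0),
                                           family = character(0)),
                site_of_origin = stats::setNames(site_of, ids),
                site_freqs = P, ancestral_freqs = p0)
  list(genotypes = g, truth = truth)
}

#' Preset condemned-population scenarios
#'
#' Two ready-made datasets shaped like the study systems the workflow is
#' built for:
#' \describe{
#'   \item{`pimelea_like`}{A shrub condemned population of 100 genets
#'     (15 full-sib families of 4 plus 33 unrelated genets) sampled with
#'     redundancy: 7 clonal genets are observed as 19 ramets (12 redundant
#'     samples), with genotyping error 0.005 so clone kinship falls just
#'     below 0.5, plus two outlying sites of 20. 2000 loci, F_ST 0.08,
#'     missingness 0.015.}
#'   \item{`eucalyptus_like`}{A tree condemned population with 18 adults
#'     and 59 seedlings (open-pollinated families from 12 seed parents),
#'     4 additional seedlings flagged as putative interspecific hybrids,
#'     and nonlocal seedling pools of 1, 3 and 4 from three outlying
#'     sites. A planted fraction (default 5%) of the loci common among
#'     adults has its minor allele erased from every local seedling, so
#'     the seedling capture ceiling phenomenon is exercisable. 2000 loci,
#'     F_ST 0.1.}
#' }
#'
#' @param preset `"pimelea_like"` or `"eucalyptus_like"`.
#' @param seed Optional integer seed.
#' @param dropout_frac For `eucalyptus_like`: fraction of adult-common
#'   loci whose minor allele is absent from all local seedlings
#'   (default 0.05).
#' @return As [generate_synthetic()]; for `eucalyptus_like` the truth
#'   additionally records `dropped_loci`.
#' @export
condemned_scenario <- function(preset = c("pimelea_like", "eucalyptus_like"),
                               seed = NULL, dropout_frac = 0.05) {
  preset <- match.arg(preset)
  if (!is.null(seed)) set.seed(seed)
  if (preset == "pimelea_like") {
    spec <- synthetic_spec(
      n_loci = 2000,
      site_sizes = c(airportlike = 93, outsiteA = 20, outsiteB = 20),
      fst = 0.08, n_families = 15, family_size = 4,
      clone_ramets = c(4L, 4L, 3L, 2L, 2L, 2L, 2L),
      error_rate = 0.005, missing_rate = 0.015, low_repro_frac = 0.1)
    return(generate_synthetic(spec))
  }

  # eucalyptus_like: adults + seedling families at the focal site
  L <- 2000
  fst <- 0.1
  p0 <- pmin(pmax(stats::rbeta(L, 0.5, 0.5), 0.02), 0.98)
  sites <- c("saltwaterlike", "gregsonlike", "clarkelike", "logielike")
  P <- vapply(sites, function(s)
    stats::rbeta(L, p0 * (1 - fst) / fst, (1 - p0) * (1 - fst) / fst),
    numeric(L))
  pf <- P[, 1]

  n_adults <- 18
  adults <- matrix(stats::rbinom(n_adults * L, 2L, rep(pf, each = n_adults)),
                   n_adults, L)
  adult_ids <- sprintf("SW_A%02d", seq_len(n_adults))

  # open-pollinated seedlings: mothers among 12 seed parents, random sires
  n_seedlings <- 59
  mothers <- sample(seq_len(12), n_seedlings, replace = TRUE)
  seedlings <- matrix(NA_integer_, n_seedlings, L)
  for (i in seq_len(n_seedlings)) {
    sire <- sample(setdiff(seq_len(n_adults), mothers[i]), 1)
    seedlings[i, ] <- .mendel_child(adults[mothers[i], ], adults[sire, ])
  }
  seedling_ids <- sprintf("SW_S%02d", seq_len(n_seedlings))

  # hybrids: flagged seedlings carrying alleles from a divergent source
  n_hyb <- 4
  p_alien <- pmin(pmax(stats::rbeta(L, 0.5, 0.5), 0.02), 0.98)
  hybrids <- matrix(NA_integer_, n_hyb, L)
  for (i in seq_len(n_hyb)) {
    dam <- adults[sample(n_adults, 1), ]
    alien <- stats::rbinom(L, 2L, p_alien)
    hybrids[i, ] <- .mendel_child(dam, alien)
  }
  hybrid_ids <- sprintf("SW_H%02d", seq_len(n_hyb))

  nonlocal_sizes <- c(gregsonlike = 1, clarkelike = 3, logielike = 4)
  nl_calls <- NULL
  nl_ids <- character(0)
  nl_site <- character(0)
  for (s in names(nonlocal_sizes)) {
    ps <- P[, s]
    for (k in seq_len(nonlocal_sizes[[s]])) {
      nl_calls <- rbind(nl_calls, stats::rbinom(L, 2L, ps))
      nl_ids <- c(nl_ids, sprintf("%s_S%02d", toupper(substr(s, 1, 2)), k))
      nl_site <- c(nl_site, s)
    }
  }

  calls <- rbind(adults, seedlings, hybrids, nl_calls)
  ids <- c(adult_ids, seedling_ids, hybrid_ids, nl_ids)
  locus_ids <- sprintf("L%05d", seq_len(L))
  dimnames(calls) <- list(ids, locus_ids)

  # guarantee a ceiling: erase the minor allele of a planted fraction of
  # adult-common loci from every local seedling (incl. hybrids)
  p_adult <- colSums(adults) / (2 * n_adults)
  maf_adult <- pmin(p_adult, 1 - p_adult)
  adult_common <- which(maf_adult > 0.03)
  n_drop <- round(dropout_frac * length(adult_common))
  dropped <- sort(sample(adult_common, n_drop))
  srows <- (n_adults + 1):(n_adults + n_seedlings + n_hyb)
  for (l in dropped) {
    calls[srows, l] <- if (p_adult[l] <= 0.5) 0L else 2L
  }

  err <- 0.003
  calls <- .apply_error(calls, err)
  calls[stats::runif(length(calls)) < 0.01] <- NA_integer_

  low <- stats::runif(L) < 0.1
  repro <- ifelse(low, stats::runif(L, 0.80, 0.96),
                  stats::runif(L, 0.961, 1.0))
  lm <- data.frame(locus_id = locus_ids, reproducibility = repro)
  sm <- data.frame(
    sample_id = ids,
    site = c(rep("saltwaterlike", n_adults + n_seedlings + n_hyb), nl_site),
    cohort = c(rep("adult", n_adults),
               rep("seedling", n_seedlings + n_hyb),
               rep("seedling", length(nl_ids))),
    is_local = c(rep(TRUE, n_adults + n_seedlings + n_hyb),
                 rep(FALSE, length(nl_ids))),
    is_hybrid = c(rep(FALSE, n_adults + n_seedlings),
                  rep(TRUE, n_hyb), rep(FALSE, length(nl_ids))),
    stringsAsFactors = FALSE)
  g <- geno_matrix(calls, locus_meta = lm, sample_meta = sm)
  truth <- list(clone_groups = list(),
                families = data.frame(sample_id = seedling_ids,
                                      family = sprintf("M%02d", mothers)),
                site_of_origin = stats::setNames(sm$site, ids),
                site_freqs = P, ancestral_freqs = p0,
                dropped_loci = locus_ids[dropped])
  list(genotypes = g, truth = truth)
}

#' Write ground truth as a tab-separated bundle
#'
#' Emits `<prefix>_clones.tsv`, `<prefix>_families.tsv`,
#' `<prefix>_sites.tsv` and `<prefix>_site_freqs.tsv`, all plain
#' tab-separated text that round-trips losslessly.
#'
#' @param truth The `truth` element of [generate_synthetic()] output.
#' @param prefix Output path prefix.
#' @return Character vector of the files written.
#' @export
write_ground_truth <- function(truth, prefix) {
  paths <- character(0)
  clone_tab <- if (length(truth$clone_groups)) {
    do.call(rbind, lapply(names(truth$clone_groups), function(gn)
      data.frame(genet = gn, sample_id = truth$clone_groups[[gn]])))
  } else data.frame(genet = character(0), sample_id = character(0))
  p <- paste0(prefix, "_clones.tsv")
  utils::write.table(clone_tab, p, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  paths <- c(paths, p)
  p <- paste0(prefix, "_families.tsv")
  utils::write.table(truth$families, p, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  paths <- c(paths, p)
  p <- paste0(prefix, "_sites.tsv")
  utils::write.table(
    data.frame(sample_id = names(truth$site_of_origin),
               site = unname(truth$site_of_origin)),
    p, sep = "\t", row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)
  p <- paste0(prefix, "_site_freqs.tsv")
  utils::write.table(as.data.frame(truth$site_freqs), p, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)
  invisible(paths)
}
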