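#' Simulated-annealing cooling schedule
#'
#' Geometric cooling control for the subset and arrangement optimizers.
#' When `t0` is `NULL` the initial temperature is set adaptively at run
#' time to the standard deviation of the objective change over 100 random
#' proposals from the starting state, which makes the schedule scale-free
#' with respect to the objective's units.
#'
#' @param t0 Initial temperature (`NULL` = adaptive, see above).
#' @param cool Geometric cooling factor per temperature step, in (0, 1).
#' @param swaps_per_temp Proposals evaluated at each temperature.
#' @param max_temps Number of temperature steps.
#' @param max_rejects Stop early after this many consecutive rejections.
#' @return List of class `sa_cooling`.
#' @export
sa_cooling <- function(t0 = NULL, cool = 0.95, swaps_per_temp = 100,
                       max_temps = 200, max_rejects = 2000) {
  stopifnot(is.null(t0) || t0 >= 0, cool > 0, cool < 1,
            swaps_per_temp >= 1, max_temps >= 1, max_rejects >= 1)
  structure(list(t0 = t0, cool = cool, swaps_per_temp = swaps_per_temp,
                 max_temps = max_temps, max_rejects = max_rejects),
            class = "sa_cooling")
}

# mean expected heterozygosity from subset column sums
.he_from_cs <- function(cs, k) {
  p <- cs / (2 * k)
  mean(2 * p * (1 - p))
}

# Core SA engine for subset selection, maximizing mean He.
# X: complete dosage matrix (candidates x loci); locked/strata by row index.
# strata: optional integer vector; strata_counts: required selected count
# per stratum (locked members count toward their stratum).
.sa_select <- function(X, n_select, locked_idx = integer(0), strata = NULL,
                       strata_counts = NULL, cooling = sa_cooling()) {
  n_cand <- nrow(X)
  ids <- rownames(X)
  if (is.null(strata)) {
    strata <- rep(1L, n_cand)
    strata_counts <- n_select
  }
  stopifnot(sum(strata_counts) == n_select)

  # initial selection: locked plus uniform draws, respecting strata counts
  sel <- rep(FALSE, n_cand)
  sel[locked_idx] <- TRUE
  for (s in seq_along(strata_counts)) {
    need <- strata_counts[s] - sum(sel & strata == s)
    if (need < 0) stop("locked members exceed stratum quota")
    pool <- which(!sel & strata == s)
    if (need > length(pool)) stop("stratum too small for requested count")
    if (need > 0) sel[pool[sample.int(length(pool), need)]] <- TRUE
  }

  swappable <- rep(TRUE, n_cand)
  swappable[locked_idx] <- FALSE
  k <- n_select
  cs <- colSums(X[sel, , drop = FALSE])
  cur <- .he_from_cs(cs, k)
  best <- cur
  best_sel <- sel

  propose <- function(sel) {
    # pick a stratum with at least one feasible swap, then an out/in pair
    feas <- vapply(seq_along(strata_counts), function(s) {
      any(sel & swappable & strata == s) && any(!sel & strata == s)
    }, logical(1))
    if (!any(feas)) return(NULL)
    s <- which(feas)
    s <- if (length(s) > 1) s[sample.int(length(s), 1)] else s
    outp <- which(sel & swappable & strata == s)
    inp <- which(!sel & strata == s)
    c(out = outp[sample.int(length(outp), 1)],
      inp = inp[sample.int(length(inp), 1)])
  }

  # adaptive T0: spread of objective deltas over random proposals
  t0 <- cooling$t0
  if (is.null(t0)) {
    deltas <- replicate(100, {
      pr <- propose(sel)
      if (is.null(pr)) return(0)
      .he_from_cs(cs + X[pr[2], ] - X[pr[1], ], k) - cur
    })
    t0 <- stats::sd(deltas)
    if (!is.finite(t0) || t0 == 0) t0 <- 1e-6
  }

  trace <- numeric(0)
  temp <- t0
  rejects <- 0L
  done <- FALSE
  for (step in seq_len(cooling$max_temps)) {
    if (done) break
    for (sw in seq_len(cooling$swaps_per_temp)) {
      pr <- propose(sel)
      if (is.null(pr)) { done <- TRUE; break }
      cs_new <- cs + X[pr[2], ] - X[pr[1], ]
      new <- .he_from_cs(cs_new, k)
      delta <- new - cur
      if (delta >= 0 || stats::runif(1) < exp(delta / temp)) {
        sel[pr[1]] <- FALSE
        sel[pr[2]] <- TRUE
        cs <- cs_new
        cur <- new
        rejects <- 0L
        if (cur > best) { best <- cur; best_sel <- sel }
      } else {
        rejects <- rejects + 1L
        if (rejects >= cooling$max_rejects) { done <- TRUE; break }
      }
    }
    trace <- c(trace, cur)
    temp <- temp * cooling$cool
  }
  list(selected = ids[best_sel], objective = best, trace = trace)
}

#' Optimize a propagation population by simulated annealing
#'
#' Selects `n_select` individuals from `candidates` so as to maximize gene
#' diversity (mean expected heterozygosity). Starting from a uniform random
#' subset that contains all `locked` members, each proposal swaps one
#' selected non-locked individual for one unselected candidate; improving
#' moves are always accepted, worsening moves with probability
#' `exp(delta / T)` under the geometric schedule in `cooling`. The
#' best-ever subset is returned.
#'
#' @param g A `geno` object; the loci used by the objective must be
#'   complete (no missing calls) over the candidates — filter with
#'   `filter_loci(g, require_complete = TRUE)` first.
#' @param candidates Candidate sample ids.
#' @param n_select Number of individuals to select.
#' @param cooling A [sa_cooling()] schedule.
#' @param locked Sample ids that must be included (e.g. plants already
#'   propagated); must satisfy `length(locked) <= n_select`.
#' @param seed Optional integer seed; fixed seed + schedule gives an
#'   identical design.
#' @param objective Objective name; only `"gene_diversity"` is available.
#' @return A `subset_design`: list with `selected`, `objective_value`
#'   (gene diversity of the best subset), `method = "sa"`, `locked`,
#'   `seed`, and `trace` (objective after each temperature step).
#' @export
optimize_subset <- function(g, candidates = NULL, n_select,
                            cooling = sa_cooling(), locked = character(0),
                            seed = NULL, objective = "gene_diversity") {
  stopifnot(inherits(g, "geno"))
  objective <- match.arg(objective, "gene_diversity")
  if (is.null(candidates)) candidates <- sample_ids(g)
  if (!all(locked %in% candidates)) stop("locked ids must be candidates")
  if (n_select < length(locked))
    stop("n_select is smaller than the number of locked members")
  if (n_select > length(candidates))
    stop("n_select exceeds the number of candidates")
  X <- g$calls[candidates, , drop = FALSE]
  if (anyNA(X))
    stop("objective requires complete data; apply filter_loci(..., ",
         "require_complete = TRUE) to the candidate matrix first")
  if (!is.null(seed)) set.seed(seed)

  if (n_select == length(locked)) {
    sel <- sort(locked)
    return(structure(list(selected = sel,
                          objective_value = gene_diversity(g, sel),
                          method = "sa", locked = locked, seed = seed,
                          trace = numeric(0)),
                     class = "subset_design"))
  }
  res <- .sa_select(X, n_select,
                    locked_idx = match(locked, candidates),
                    cooling = cooling)
  structure(list(selected = sort(res$selected),
                 objective_value = res$objective,
                 method = "sa", locked = locked, seed = seed,
                 trace = res$trace),
            class = "subset_design")
}

#' @export
print.subset_design <- function(x, ...) {
  cat(sprintf("<subset_design> %s, N_P = %d, He = %.4f",
              x$method, length(x$selected), x$objective_value))
  if (!is.null(x$proportion_local) && !is.na(x$proportion_local))
    cat(sprintf(", local = %.2f", x$proportion_local))
  cat("\n")
  invisible(x)
}

#' Diversity-vs-local trade-off by epsilon-constraint optimization
#'
#' Characterizes the trade-off between maximizing gene diversity and
#' maximizing the representation of the local (condemned) population when
#' a collection may be supplemented with nonlocal individuals. For each
#' admissible count `c` of nonlocal members (0 up to
#' `min(n_select, length(nonlocal))`), gene diversity is maximized under
#' the constraint of exactly `c` nonlocal and `n_select - c` local members,
#' giving one point of a discrete trade-off front.
#'
#' @param g A `geno` object (complete loci over all candidates).
#' @param local,nonlocal Candidate sample ids in the two pools.
#' @param n_select Collection size.
#' @param cooling A [sa_cooling()] schedule.
#' @param seed Optional integer seed.
#' @return List of `subset_design` objects, each with
#'   `proportion_local = (n_select - c) / n_select` and `n_nonlocal = c`.
#' @export
multiobjective_front <- function(g, local, nonlocal, n_select,
                                 cooling = sa_cooling(), seed = NULL) {
  stopifnot(inherits(g, "geno"))
  if (n_select > length(local) + length(nonlocal))
    stop("n_select exceeds the candidate pool")
  candidates <- c(local, nonlocal)
  X <- g$calls[candidates, , drop = FALSE]
  if (anyNA(X))
    stop("objective requires complete data over the candidate pool")
  if (!is.null(seed)) set.seed(seed)
  strata <- rep(1:2, c(length(local), length(nonlocal)))
  c_max <- min(n_select, length(nonlocal))
  out <- list()
  for (c_nl in 0:c_max) {
    n_local <- n_select - c_nl
    if (n_local > length(local)) next
    res <- .sa_select(X, n_select, strata = strata,
                      strata_counts = c(n_local, c_nl), cooling = cooling)
    out[[length(out) + 1]] <- structure(
      list(selected = sort(res$selected), objective_value = res$objective,
           method = "sa", locked = character(0), seed = seed,
           n_nonlocal = c_nl, proportion_local = n_local / n_select,
           trace = res$trace),
      class = "subset_design")
  }
  out
}

#' Sweep propagation-population sizes: optimized vs random
#'
#' For each size, runs one simulated-annealing optimization and a
#' random-selection baseline, and evaluates the allele-capture proportion
#' of each against a common-locus reference set.
#'
#' @param g A `geno` object (complete loci over candidates).
#' @param candidates Candidate sample ids (default: all).
#' @param sizes Ascending vector of subset sizes, e.g. `seq(16, 64, 4)`.
#' @param reference_common Reference locus ids for capture.
#' @param cooling A [sa_cooling()] schedule.
#' @param n_random_reps Random subsets per size (default 100).
#' @param seed Optional integer seed.
#' @return List with `table` (one row per size and arm: size, method,
#'   gene_diversity, capture, capture_sd) and `designs` (the optimized
#'   `subset_design` per size).
#' @export
size_sweep <- function(g, candidates = NULL, sizes, reference_common,
                       cooling = sa_cooling(), n_random_reps = 100,
                       seed = NULL) {
  stopifnot(inherits(g, "geno"), !is.unsorted(sizes))
  if (is.null(candidates)) candidates <- sample_ids(g)
  if (!is.null(seed)) set.seed(seed)
  designs <- list()
  rows <- list()
  for (np in sizes) {
    des <- optimize_subset(g, candidates, np, cooling = cooling)
    cap <- capture_proportion(g, des$selected, reference_common)
    designs[[as.character(np)]] <- des
    rows[[length(rows) + 1]] <- data.frame(
      size = np, method = "optimized",
      gene_diversity = des$objective_value,
      capture = cap$proportion, capture_sd = NA_real_)
    base <- random_baseline(g, np, reference_common, n_reps = n_random_reps,
                            candidates = candidates)
    rows[[length(rows) + 1]] <- data.frame(
      size = np, method = "random",
      gene_diversity = base$mean_gene_diversity,
      capture = base$mean_proportion, capture_sd = base$sd_proportion)
  }
  list(table = do.call(rbind, rows), designs = designs)
}

#' Nestedness of optimized designs across sizes
#'
#' Small optimized propagation populations tend to be subsets of larger
#' ones; this quantifies that. The membership matrix lists, for every
#' individual selected in any design, whether it appears at each size
#' (rows ordered by first appearance). The score is the fraction of
#' (individual, consecutive-size) cases where membership at the smaller
#' size implies membership at the larger.
#'
#' @param designs List of `subset_design` objects sorted by size.
#' @return List with `membership` (0/1 matrix, individuals x sizes) and
#'   `score` in \[0, 1\] (1 = perfectly nested).
#' @export
nestedness <- function(designs) {
  sizes <- vapply(designs, function(d) length(d$selected), integer(1))
  if (is.unsorted(sizes)) stop("designs must be sorted by size")
  all_ids <- unique(unlist(lapply(designs, `[[`, "selected")))
  first_at <- vapply(all_ids, function(id) {
    which(vapply(designs, function(d) id %in% d$selected, logical(1)))[1]
  }, integer(1))
  ord <- order(first_at, all_ids)
  all_ids <- all_ids[ord]
  mem <- vapply(designs, function(d) as.integer(all_ids %in% d$selected),
                integer(length(all_ids)))
  mem <- matrix(mem, nrow = length(all_ids),
                dimnames = list(all_ids, sizes))
  n_case <- 0L
  n_nested <- 0L
  for (j in seq_len(ncol(mem) - 1)) {
    small <- mem[, j] == 1
    n_case <- n_case + sum(small)
    n_nested <- n_nested + sum(small & mem[, j + 1] == 1)
  }
  list(membership = mem,
       score = if (n_case > 0) n_nested / n_case else NA_real_)
}

#' Write subset designs as tab-separated text
#' @param designs A `subset_design` or list of them.
#' @param path Output path.
#' @export
write_designs <- function(designs, path) {
  if (inherits(designs, "subset_design")) designs <- list(designs)
  rows <- do.call(rbind, lapply(designs, function(d) {
    data.frame(size = length(d$selected), method = d$method,
               sample_id = d$selected,
               locked = as.integer(d$selected %in% d$locked),
               gene_diversity = d$objective_value,
               proportion_local = if (is.null(d$proportion_local)) NA_real_
                                  else d$proportion_local,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
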