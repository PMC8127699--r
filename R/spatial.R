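#' Planting layouts: clumps or a regular grid
#'
#' Clumped layouts place groups of `clump_size` positions close together
#' (members of a clump on a small ring of radius
#' `within_spacing / (2 sin(pi / clump_size))`, so adjacent ring positions
#' are `within_spacing` metres apart), with clump centres on a square grid
#' `clump_spacing` metres apart. Clumped plantings are used to promote seed
#' set in eucalypts; a regular grid with spacing `within_spacing` is also
#' supported.
#'
#' @param n_positions Number of planting positions.
#' @param clump_size Positions per clump (default 5).
#' @param clump_spacing Distance between clump centres in metres
#'   (default 30).
#' @param within_spacing Distance between neighbouring positions within a
#'   clump (or between grid neighbours) in metres (default 3).
#' @param mode `"clumped"` or `"grid"`.
#' @return A `layout` data frame with columns `x`, `y` (metres) and
#'   `clump`.
#' @export
clumped_layout <- function(n_positions, clump_size = 5, clump_spacing = 30,
                           within_spacing = 3,
                           mode = c("clumped", "grid")) {
  mode <- match.arg(mode)
  stopifnot(n_positions >= 1, within_spacing > 0)
  if (mode == "grid") {
    side <- ceiling(sqrt(n_positions))
    idx <- seq_len(n_positions) - 1
    out <- data.frame(x = (idx %% side) * within_spacing,
                      y = (idx %/% side) * within_spacing,
                      clump = NA_integer_)
    class(out) <- c("planting_layout", "data.frame")
    return(out)
  }
  stopifnot(clump_size >= 1, clump_spacing > within_spacing)
  n_clumps <- ceiling(n_positions / clump_size)
  side <- ceiling(sqrt(n_clumps))
  r <- if (clump_size == 1) 0 else
    within_spacing / (2 * sin(pi / clump_size))
  rows <- list()
  pos <- 0
  for (cl in seq_len(n_clumps)) {
    cx <- ((cl - 1) %% side) * clump_spacing
    cy <- ((cl - 1) %/% side) * clump_spacing
    m <- min(clump_size, n_positions - pos)
    ang <- 2 * pi * (seq_len(m) - 1) / clump_size
    rows[[cl]] <- data.frame(x = cx + r * cos(ang), y = cy + r * sin(ang),
                             clump = cl)
    pos <- pos + m
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("planting_layout", "data.frame")
  out
}

# pairwise Euclidean distances of a layout; errors on coincident points
.layout_dist <- function(layout) {
  d <- as.matrix(stats::dist(layout[, c("x", "y")]))
  if (any(d[upper.tri(d)] <= 0))
    stop("layout has coincident positions; all pairwise distances must be > 0")
  d
}

# genetic similarity matrix from kinship (floored, diagonal zeroed)
.similarity <- function(kinship, plants, similarity_floor = 0) {
  km <- unclass(kinship)
  missing_p <- setdiff(plants, rownames(km))
  if (length(missing_p))
    stop("plants absent from kinship matrix: ",
         paste(missing_p, collapse = ", "))
  G <- km[plants, plants, drop = FALSE]
  G <- pmax(G, similarity_floor)
  diag(G) <- 0
  G
}

#' Spatial-genetic objective f of an arrangement
#'
#' `f = (1 / n_pairs) * sum over unordered pairs of G_ij / S_ij`, where
#' `S_ij` is the Euclidean distance in metres between the positions of
#' plants `i` and `j`, and `G_ij` is their genetic similarity, taken as
#' kinship floored at `similarity_floor` (default 0, so negative kinship
#' estimates do not reward proximity). Large `f` means genetically similar
#' plants sit close together; the optimizer minimizes it. Units are
#' 1/metres.
#'
#' @param plants Character vector of plant ids, in position order: plant
#'   `i` stands at `layout` row `i`.
#' @param layout A `layout` data frame (see [clumped_layout()]).
#' @param kinship A `kinship` object covering the plants.
#' @param similarity_floor Lower bound applied to kinship (default 0).
#' @return Scalar `f`.
#' @export
objective_f <- function(plants, layout, kinship, similarity_floor = 0) {
  stopifnot(length(plants) == nrow(layout))
  D <- .layout_dist(layout)
  G <- .similarity(kinship, plants, similarity_floor)
  n_pairs <- length(plants) * (length(plants) - 1) / 2
  sum((G / D)[upper.tri(D)]) / n_pairs
}

#' Optimize a planting arrangement by simulated annealing
#'
#' Starts from a uniform random assignment of plants to positions and
#' proposes swaps of the positions of two plants, minimizing [objective_f()]
#' under the acceptance rule of the [sa_cooling()] schedule. Returns the
#' best-ever arrangement, together with the initial random arrangement so
#' the paired before/after comparison can be reported.
#'
#' @param plants Plant ids; must equal the number of layout positions.
#' @param layout A `layout` data frame.
#' @param kinship A `kinship` object covering the plants.
#' @param cooling A [sa_cooling()] schedule.
#' @param similarity_floor Passed to [objective_f()].
#' @param seed Optional integer seed.
#' @return An `arrangement`: list with `plants` (best-found position
#'   order), `f_value`, `initial_plants`, `initial_f`, `layout`, `trace`.
#' @export
anneal_arrangement <- function(plants, layout, kinship,
                               cooling = sa_cooling(),
                               similarity_floor = 0, seed = NULL) {
  n <- length(plants)
  stopifnot(n == nrow(layout), n >= 2)
  if (!is.null(seed)) set.seed(seed)
  invD <- 1 / .layout_dist(layout)
  diag(invD) <- 0
  G <- .similarity(kinship, plants, similarity_floor)
  n_pairs <- n * (n - 1) / 2
  # f for a permutation: perm[i] = index of the plant standing at position i
  fval <- function(perm) sum(G[perm, perm] * invD) / 2 / n_pairs

  perm <- sample.int(n)
  cur <- fval(perm)
  init_perm <- perm
  init_f <- cur
  best <- cur
  best_perm <- perm

  t0 <- cooling$t0
  if (is.null(t0)) {
    deltas <- replicate(100, {
      ij <- sample.int(n, 2)
      p2 <- perm
      p2[ij] <- p2[rev(ij)]
      fval(p2) - cur
    })
    t0 <- stats::sd(deltas)
    if (!is.finite(t0) || t0 == 0) t0 <- 1e-9
  }

  trace <- numeric(0)
  temp <- t0
  rejects <- 0L
  done <- FALSE
  for (step in seq_len(cooling$max_temps)) {
    if (done) break
    for (sw in seq_len(cooling$swaps_per_temp)) {
      ij <- sample.int(n, 2)
      p2 <- perm
      p2[ij] <- p2[rev(ij)]
      new <- fval(p2)
      delta <- cur - new  # minimizing: improvement when new < cur
      if (delta >= 0 || stats::runif(1) < exp(delta / temp)) {
        perm <- p2
        cur <- new
        rejects <- 0L
        if (cur < best) { best <- cur; best_perm <- perm }
      } else {
        rejects <- rejects + 1L
        if (rejects >= cooling$max_rejects) { done <- TRUE; break }
      }
    }
    trace <- c(trace, cur)
    temp <- temp * cooling$cool
  }
  structure(list(plants = plants[best_perm], f_value = best,
                 initial_plants = plants[init_perm], initial_f = init_f,
                 layout = layout, trace = trace),
            class = "arrangement")
}

#' @export
print.arrangement <- function(x, ...) {
  cat(sprintf("<arrangement> %d plants, f = %.6f (initial random f = %.6f)\n",
              length(x$plants), x$f_value, x$initial_f))
  invisible(x)
}

#' Count close pairs of genetically similar plants
#'
#' @param plants Plant ids in position order.
#' @param layout A `layout` data frame.
#' @param kinship A `kinship` object.
#' @param kin_min Kinship threshold defining "genetically similar"
#'   (default 0.12).
#' @param dist_max Distance below/at which a similar pair counts as
#'   "close", metres (default 25).
#' @return Number of pairs with kinship >= `kin_min` and distance <=
#'   `dist_max`.
#' @export
close_similar_pairs <- function(plants, layout, kinship, kin_min = 0.12,
                                dist_max = 25) {
  D <- .layout_dist(layout)
  km <- unclass(kinship)[plants, plants, drop = FALSE]
  up <- upper.tri(D)
  sum(km[up] >= kin_min & D[up] <= dist_max, na.rm = TRUE)
}

#' Null distribution of close similar pairs over random arrangements
#'
#' Generates `n_reps` uniform random assignments of the plants to the
#' layout positions and counts, for each, the pairs of genetically similar
#' plants (`kinship >= kin_min`) that are close together
#' (`distance <= dist_max`). Also returns, for each replicate, the
#' distances between all similar pairs, for distance-histogram summaries.
#'
#' @inheritParams close_similar_pairs
#' @param n_reps Number of random arrangements (default 1000).
#' @param seed Optional integer seed.
#' @return List with `counts` (integer vector, one per replicate) and
#'   `distances` (list of numeric vectors: distances of similar pairs per
#'   replicate).
#' @export
null_arrangements <- function(plants, layout, kinship, n_reps = 1000,
                              kin_min = 0.12, dist_max = 25, seed = NULL) {
  stopifnot(n_reps >= 1, length(plants) == nrow(layout))
  if (!is.null(seed)) set.seed(seed)
  D <- .layout_dist(layout)
  km <- unclass(kinship)[plants, plants, drop = FALSE]
  up <- upper.tri(D)
  n <- length(plants)
  counts <- integer(n_reps)
  distances <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    perm <- sample.int(n)
    kperm <- km[perm, perm]
    sim <- !is.na(kperm[up]) & kperm[up] >= kin_min
    dd <- D[up][sim]
    distances[[r]] <- dd
    counts[r] <- sum(dd <= dist_max)
  }
  list(counts = counts, distances = distances)
}

#' Write a layout/arrangement as tab-separated text
#' @param arrangement An `arrangement` object.
#' @param path Output path.
#' @export
write_arrangement <- function(arrangement, path) {
  tab <- data.frame(plant_id = arrangement$plants,
                    x = arrangement$layout$x, y = arrangement$layout$y,
                    clump = arrangement$layout$clump)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
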