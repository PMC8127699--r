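test_that("degenerate selections need no search", {
  set.seed(301)
  g <- hw_geno(8, runif(40, 0.1, 0.9))
  # selecting everyone returns the full population value
  d <- optimize_subset(g, n_select = 8, seed = 1)
  expect_setequal(d$selected, sample_ids(g))
  expect_equal(d$objective_value, gene_diversity(g))
  # a fully locked selection is returned as-is
  locked <- sample_ids(g)[1:3]
  d2 <- optimize_subset(g, n_select = 3, locked = locked, seed = 1)
  expect_setequal(d2$selected, locked)
  # locked members always included in a real search
  d3 <- optimize_subset(g, n_select = 5, locked = locked, seed = 2,
                        cooling = fast_cooling())
  expect_true(all(locked %in% d3$selected))
  expect_error(optimize_subset(g, n_select = 2, locked = locked),
               "locked")
  expect_error(optimize_subset(g, n_select = 9), "exceeds")
})

test_that("same seed and schedule give an identical design", {
  set.seed(302)
  g <- hw_geno(20, runif(60, 0.05, 0.95))
  d1 <- optimize_subset(g, n_select = 6, seed = 77)
  d2 <- optimize_subset(g, n_select = 6, seed = 77)
  expect_identical(d1$selected, d2$selected)
  expect_identical(d1$trace, d2$trace)
})

test_that("zero-temperature annealing is a greedy hill-climb", {
  set.seed(303)
  g <- hw_geno(15, runif(50, 0.05, 0.95))
  d <- optimize_subset(g, n_select = 5, seed = 5,
                       cooling = sa_cooling(t0 = 0, max_temps = 50))
  # only non-worsening moves were accepted, so the trace never decreases
  expect_false(is.unsorted(d$trace))
  expect_equal(d$objective_value, max(d$trace))
})

test_that("missing data in the objective is rejected with guidance", {
  set.seed(304)
  x <- hw_matrix(10, runif(30, 0.2, 0.8))
  x[1, 1] <- NA
  expect_error(optimize_subset(geno_matrix(x), n_select = 4),
               "require_complete")
})

test_that("the constrained front matches exhaustive constrained optima on a small instance", {
  set.seed(305)
  # nonlocal pool carries novel alleles: 20 shared polymorphic loci plus
  # 20 loci monomorphic in the local population but variable nonlocally
  p_shared <- runif(20, 0.3, 0.7)
  Xl <- cbind(hw_matrix(6, p_shared, ids = paste0("loc", 1:6)),
              matrix(0L, 6, 20))
  Xn <- cbind(hw_matrix(3, p_shared, ids = paste0("non", 1:3)),
              hw_matrix(3, rep(0.5, 20)))
  colnames(Xl) <- colnames(Xn) <- paste0("L", 1:40)
  g <- geno_matrix(rbind(Xl, Xn))
  local <- paste0("loc", 1:6)
  nonlocal <- paste0("non", 1:3)
  front <- multiobjective_front(g, local, nonlocal, n_select = 4, seed = 9)
  expect_length(front, 4)  # c = 0..3
  expect_equal(vapply(front, `[[`, numeric(1), "proportion_local"),
               c(4, 3, 2, 1) / 4)
  X <- g$calls
  for (i in seq_along(front)) {
    c_nl <- front[[i]]$n_nonlocal
    sel_n <- if (c_nl > 0) combn(nonlocal, c_nl, simplify = FALSE) else
      list(character(0))
    sel_l <- combn(local, 4 - c_nl, simplify = FALSE)
    exact <- max(vapply(sel_l, function(a)
      max(vapply(sel_n, function(b) he_oracle(X[c(a, b), , drop = FALSE]),
                 numeric(1))), numeric(1)))
    expect_equal(front[[i]]$objective_value, exact, tolerance = 1e-12)
    expect_equal(sum(front[[i]]$selected %in% nonlocal), c_nl)
  }
  # novel nonlocal alleles make diversity non-decreasing in c
  he <- vapply(front, `[[`, numeric(1), "objective_value")
  expect_false(is.unsorted(he))
})

test_that("the nonlocal count is capped by the pool size", {
  set.seed(306)
  g <- hw_geno(12, runif(30, 0.1, 0.9))
  front <- multiobjective_front(g, sample_ids(g)[1:10], sample_ids(g)[11:12],
                                n_select = 5, seed = 3,
                                cooling = fast_cooling())
  expect_equal(vapply(front, `[[`, numeric(1), "n_nonlocal"), 0:2)
})

test_that("a size sweep over the whole population captures everything in both arms", {
  set.seed(307)
  g <- hw_geno(10, runif(50, 0.1, 0.9))
  ref <- common_loci(g, maf_min = 0.02)
  sw <- size_sweep(g, sizes = 10, reference_common = ref,
                   n_random_reps = 5, cooling = fast_cooling(), seed = 4)
  expect_true(all(sw$table$capture == 1))
})

test_that("nestedness scores perfectly nested and disjoint designs correctly", {
  mk <- function(ids) structure(list(selected = ids, objective_value = 0,
                                     method = "sa", locked = character(0)),
                                class = "subset_design")
  nested <- list(mk(c("a", "b")), mk(c("a", "b", "c")),
                 mk(c("a", "b", "c", "d")))
  expect_equal(nestedness(nested)$score, 1)
  disjoint <- list(mk(c("a", "b")), mk(c("c", "d")))
  expect_equal(nestedness(disjoint)$score, 0)
  # random designs: score matches a direct recount
  set.seed(308)
  pool <- letters[1:12]
  des <- list(mk(sample(pool, 3)), mk(sample(pool, 5)), mk(sample(pool, 7)))
  n <- nestedness(des)
  cases <- 0; hits <- 0
  for (j in 1:2) {
    for (id in des[[j]]$selected) {
      cases <- cases + 1
      hits <- hits + (id %in% des[[j + 1]]$selected)
    }
  }
  expect_equal(n$score, hits / cases)
  # membership matrix is first-appearance ordered
  expect_equal(rownames(n$membership)[1:3], sort(des[[1]]$selected))
  expect_error(nestedness(rev(nested)), "sorted")
})
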