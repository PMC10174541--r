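test_that("fast non-dominated sort matches the brute-force oracle", {
  set.seed(61)
  for (rep in 1:25) {
    n <- sample(5:50, 1)
    m <- sample(2:3, 1)
    M <- matrix(runif(n * m), n, m)
    fronts <- fast_non_dominated_sort(M, senses = rep("min", m))
    oracle <- brute_force_fronts(M)
    expect_equal(length(fronts), length(oracle))
    for (k in seq_along(fronts)) {
      expect_setequal(fronts[[k]], oracle[[k]])
    }
  }
})

test_that("sorting handles degenerate inputs and maximization senses", {
  expect_equal(fast_non_dominated_sort(matrix(numeric(0), 0, 2)), list())
  expect_equal(fast_non_dominated_sort(matrix(c(1, 2), 1, 2)), list(1L))
  chain <- cbind(c(1, 2, 3), c(9, 8, 7))
  expect_equal(fast_non_dominated_sort(chain, c("min", "min")),
               list(c(1L, 2L, 3L)))
  # same chain under (min, max): row 1 dominates all
  expect_equal(fast_non_dominated_sort(chain, c("min", "max")),
               list(1L, 2L, 3L))
})

test_that("crowding distance: boundaries infinite, spacing hand-checked", {
  expect_equal(crowding_distance(cbind(1, 2)), Inf)
  expect_equal(crowding_distance(cbind(c(1, 2), c(4, 3))), c(Inf, Inf))
  # three evenly spaced collinear points: middle gets 1 per objective
  tri <- cbind(c(0, 5, 10), c(10, 5, 0))
  expect_equal(crowding_distance(tri), c(Inf, 2, Inf))
  # identical objectives: interior distances zero
  same <- matrix(3, 4, 2)
  d <- crowding_distance(same)
  expect_equal(sum(is.infinite(d)), 2L)
  expect_equal(d[is.finite(d)], c(0, 0))
  # infinities land exactly on per-objective extremes when values are distinct
  set.seed(62)
  front <- cbind(sort(runif(8)), sort(runif(8), decreasing = TRUE))
  d <- crowding_distance(front)
  extreme <- front[, 1] %in% range(front[, 1]) |
    front[, 2] %in% range(front[, 2])
  expect_equal(is.infinite(d), extreme)
})

test_that("ideal-point selection minimizes the distance to (m, n)", {
  front <- rbind(c(10, 90), c(5, 80))
  idx <- ideal_point_select(front, m = 0, n = 100)
  expect_equal(as.integer(idx), 1L)  # dist 14.14 beats 20.62
  expect_equal(attr(idx, "distance"), c(sqrt(200), sqrt(425)))
  expect_equal(as.integer(ideal_point_select(front[2, , drop = FALSE],
                                             0, 100)), 1L)
  # a front containing (m, n) itself wins with distance 0
  idx0 <- ideal_point_select(rbind(c(4, 70), c(2, 88)), m = 2, n = 88)
  expect_equal(as.integer(idx0), 2L)
  # exact ties break toward lower contamination
  tie <- rbind(c(3, 4), c(4, 3))
  expect_equal(as.integer(ideal_point_select(tie, 0, 0)), 1L)
  expect_error(ideal_point_select(matrix(numeric(0), 0, 2), 0, 0), "empty")
})

test_that("NSGA-II solves the SCH benchmark", {
  sch <- function(X) cbind(X[, 1]^2, (X[, 1] - 2)^2)
  res <- nsga2(sch, n_var = 1, lower = -10, upper = 10,
               senses = c("min", "min"), pop_size = 60, generations = 100,
               seed = 3)
  x1 <- res$X[res$fronts[[1]], 1]
  inside <- mean(x1 >= -0.05 & x1 <= 2.05)
  expect_gte(inside, 0.95)
})

test_that("offspring always respect the box bounds", {
  set.seed(63)
  spiky <- function(X) cbind(rowSums(X^2), rowSums((X - 1)^2))
  res <- nsga2(spiky, n_var = 3, lower = c(-1, 0, 2), upper = c(1, 0.5, 5),
               senses = c("min", "min"), pop_size = 20, generations = 40,
               mutation_rate = 0.5, seed = 4)
  expect_true(all(res$X >= matrix(c(-1, 0, 2), 20, 3, byrow = TRUE) - 1e-12))
  expect_true(all(res$X <= matrix(c(1, 0.5, 5), 20, 3, byrow = TRUE) + 1e-12))
})

test_that("with variation disabled, elitism admits no novelty and keeps the
           per-objective optima", {
  sch <- function(X) cbind(X[, 1]^2, (X[, 1] - 2)^2)
  set.seed(11)
  init <- matrix(runif(30, -10, 10), 30, 1)
  # reconstruct the seeded initial population the engine draws
  res <- nsga2(sch, 1, -10, 10, pop_size = 30, generations = 25,
               crossover_rate = 0, mutation_rate = 0, seed = 11,
               utopia = c(0, 0))
  set.seed(11)
  P0 <- -10 + matrix(runif(30), 30, 1) * 20
  expect_true(all(res$X[, 1] %in% P0[, 1]))
  obj0 <- sch(P0)
  expect_equal(min(res$objectives[, 1]), min(obj0[, 1]))
  expect_equal(min(res$objectives[, 2]), min(obj0[, 2]))
  # elitist utopia-distance trace never increases
  expect_true(all(diff(res$trace) <= 1e-12))
})

test_that("runs are reproducible given the seed", {
  sch <- function(X) cbind(X[, 1]^2, (X[, 1] - 2)^2)
  a <- nsga2(sch, 1, -10, 10, pop_size = 20, generations = 20, seed = 9)
  b <- nsga2(sch, 1, -10, 10, pop_size = 20, generations = 20, seed = 9)
  expect_identical(a$X, b$X)
})
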