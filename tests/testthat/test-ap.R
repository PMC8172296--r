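test_that("negative squared Euclidean similarity follows the formula", {
  S <- similarity_matrix(matrix(c(0, 3), ncol = 1))
  expect_equal(S[1, 2], -9)
  expect_equal(S[2, 1], -9)
  expect_true(is.na(S[1, 1]))

  S2 <- similarity_matrix(matrix(c(0, 0, 1, 1), 2, byrow = TRUE))
  expect_equal(S2[1, 2], -2)

  same <- similarity_matrix(matrix(1, 3, 2))
  expect_equal(same[row(same) != col(same)], rep(0, 6))

  expect_error(similarity_matrix(matrix(numeric(0), 0, 2)), "at least one")
})

test_that("preferences fill the diagonal as a scalar or the off-diagonal median", {
  S <- matrix(0, 3, 3)
  expect_equal(diag(set_preference(S, -26.62758)), rep(-26.62758, 3))
  expect_equal(diag(set_preference(S, 0)), rep(0, 3))

  S2 <- matrix(0, 4, 4)
  S2[lower.tri(S2)] <- -(1:6)
  S2 <- S2 + t(S2)   # off-diagonals are {-1..-6} twice; median -3.5
  expect_equal(diag(set_preference(S2, "median")), rep(-3.5, 4))
})

test_that("message updates match naive loop oracles", {
  S <- matrix(c(-5, -2, -4, -5), 2, byrow = TRUE)
  R <- ramrsgl:::update_responsibility(S, matrix(0, 2, 2), matrix(0, 2, 2), 0)
  expect_equal(R[1, 2], 3)   # -2 - (-5)
  expect_equal(R[1, 1], -3)  # -5 - (-2)

  set.seed(31)
  for (n in c(3, 4, 6)) {
    S <- matrix(rnorm(n * n), n)
    A <- matrix(rnorm(n * n), n)
    R0 <- matrix(rnorm(n * n), n)
    expect_equal(ramrsgl:::update_responsibility(S, R0, A, 0),
                 oracle_responsibility(S, A), tolerance = 1e-12)
    expect_equal(ramrsgl:::update_availability(R0, A, 0),
                 oracle_availability(R0), tolerance = 1e-12)
    # damping interpolates between current and candidate messages
    d <- 0.7
    expect_equal(ramrsgl:::update_responsibility(S, R0, A, d),
                 d * R0 + (1 - d) * oracle_responsibility(S, A),
                 tolerance = 1e-12)
  }
})

test_that("availability handles the small closed-form case and nonpositive R", {
  R <- matrix(c(-3, 3, 1, -3), 2, byrow = TRUE)
  A <- ramrsgl:::update_availability(R, matrix(0, 2, 2), 0)
  expect_equal(A[1, 2], -3)  # min(0, r(2,2) + 0) = -3
  expect_equal(A[2, 2], 3)   # max(0, r(1,2)) = 3

  R2 <- matrix(c(0, -1, -2, 0), 2, byrow = TRUE)
  A2 <- ramrsgl:::update_availability(R2, matrix(0, 2, 2), 0)
  expect_equal(A2, matrix(0, 2, 2))
})

test_that("ap_cluster is exemplar-optimal on small well-separated instances", {
  # two tight far pairs: the best exemplar set has one exemplar per pair
  pts <- matrix(c(0, 0.1, 100, 100.1), ncol = 1)
  S <- set_preference(similarity_matrix(pts), "median")
  res <- ap_cluster(S)
  best <- oracle_best_subset(S)
  expect_true(res$converged)
  expect_equal(length(res$exemplars), 2L)
  expect_equal(res$net_similarity, best$net, tolerance = 1e-9)
  expect_setequal(res$labels[1:2], res$labels[1])
  expect_setequal(res$labels[3:4], res$labels[3])

  # five points, two clumps: exhaustive subset oracle over 2^5 - 1 sets
  pts5 <- matrix(c(0, 0.2, 0.4, 50, 50.3), ncol = 1)
  S5 <- set_preference(similarity_matrix(pts5), "median")
  res5 <- ap_cluster(S5)
  best5 <- oracle_best_subset(S5)
  expect_equal(res5$net_similarity, best5$net, tolerance = 1e-9)
})

test_that("ap_cluster result invariants hold", {
  res1 <- ap_cluster(matrix(-1, 1, 1))
  expect_identical(res1$exemplars, 1L)
  expect_identical(res1$labels, 1L)

  set.seed(9)
  pts <- rbind(matrix(rnorm(10, 0), 5), matrix(rnorm(10, 8), 5))
  S <- set_preference(similarity_matrix(pts), "median")
  res <- ap_cluster(S)
  # labels partition the points and each cluster contains its exemplar
  expect_true(all(res$labels %in% res$exemplars))
  expect_identical(res$labels[res$exemplars], res$exemplars)
  # stored similarity sums match recomputation from the labels
  non_ex <- setdiff(seq_len(10), res$exemplars)
  expect_equal(res$sum_of_similarities,
               sum(S[cbind(non_ex, res$labels[non_ex])]))
  expect_equal(res$net_similarity,
               res$sum_of_similarities + sum(diag(S)[res$exemplars]))
  # determinism
  expect_identical(ap_cluster(S), res)
})

test_that("raising the common preference never decreases the cluster count", {
  set.seed(12)
  pts <- matrix(rnorm(16), 8, 2)
  S <- similarity_matrix(pts)
  prefs <- c(-50, -10, -3, -1, -0.1)
  counts <- vapply(prefs, function(p)
    length(ap_cluster(set_preference(S, p))$exemplars), 1L)
  expect_true(all(diff(counts) >= 0))
})
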