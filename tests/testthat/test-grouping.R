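test_that("per-class clustering groups correlated genes", {
  # one class: two genes with identical profiles plus one distant gene
  set.seed(2)
  f <- rnorm(8)
  D <- cbind(g1 = f, g2 = 2 * f + 1, g3 = rnorm(8))
  v <- cluster_per_class(D, rep(1L, 8))
  expect_length(v, 1L)
  expect_equal(v[[1]][1], v[[1]][2])
  # exhaustive oracle agrees that the identical pair shares an exemplar
  Z <- scale(D); Z[!is.finite(Z)] <- 0
  S <- set_preference(similarity_matrix(t(Z)), "median")
  best <- oracle_best_subset(S)
  lab_oracle <- apply(S[, best$exemplars, drop = FALSE], 1, which.max)
  lab_oracle[best$exemplars] <- seq_along(best$exemplars)
  expect_equal(unname(lab_oracle[1]), unname(lab_oracle[2]))

  # all genes identical within a class -> a single cluster
  D2 <- matrix(rep(rnorm(6), 4), 6, 4)
  v2 <- cluster_per_class(D2, rep(1L, 6))
  expect_equal(v2[[1]], rep(1L, 4))

  expect_error(cluster_per_class(D, c(1, 1, 1, 1, 1, 1, 1, 2)), "at least 2")
})

test_that("overlap expansion builds the documented column and group layout", {
  A <- matrix(c(10, 20), 1, 2)
  ex <- expand_matrix(A, list(c(1L, 1L), c(1L, 2L)))
  expect_equal(ncol(ex$matrix), 4L)
  expect_equal(ex$groups$global_groups, c(1L, 1L, 2L, 3L))
  expect_identical(ex$groups$V, 3L)
  expect_equal(ex$groups$group_sizes, c(2L, 1L, 1L))
  expect_equal(as.numeric(ex$matrix), c(10, 20, 10, 20))

  # K = 1, one group: expansion is the identity
  B <- matrix(rnorm(12), 3, 4)
  ex1 <- expand_matrix(B, list(rep(1L, 4)))
  expect_equal(unname(ex1$matrix), unname(B))
  expect_identical(ex1$groups$V, 1L)

  expect_error(expand_matrix(B, list(c(1L, 1L))), "length")
})

test_that("group sizes and per-gene copy counts are conserved", {
  set.seed(4)
  M <- 30; K <- 3
  inds <- lapply(seq_len(K), function(t) sample(1:4, M, replace = TRUE))
  inds <- lapply(inds, function(v) match(v, unique(v)))
  A <- matrix(rnorm(5 * M), 5, M)
  ex <- expand_matrix(A, inds)
  gs <- ex$groups
  expect_equal(sum(gs$group_sizes), K * M)
  expect_equal(gs$V, sum(vapply(inds, max, 1L)))
  expect_equal(as.vector(table(gs$column_map$gene)), rep(K, M))
  # groups are contiguous blocks in class order
  expect_false(is.unsorted(gs$global_groups))
  expect_false(is.unsorted(gs$column_map$class))
})

test_that("apply_expansion reproduces training rows and copy counts", {
  set.seed(6)
  M <- 12
  inds <- list(sample(rep(1:3, each = 4)), sample(rep(1:2, each = 6)))
  A <- matrix(rnorm(4 * M), 4, M)
  ex <- expand_matrix(A, inds)
  for (i in 1:4) {
    expect_equal(unname(apply_expansion(A[i, ], ex$groups)),
                 unname(ex$matrix[i, ]))
  }
  expect_equal(apply_expansion(rep(7, M), ex$groups), rep(7, 2 * M))
  x <- rnorm(M)
  xb <- apply_expansion(x, ex$groups)
  expect_equal(as.vector(table(match(xb, x))), rep(2L, M))
  expect_error(apply_expansion(rnorm(M + 1), ex$groups), "length")
})

test_that("gene reliability and weights respond to noise as specified", {
  Eb <- cbind(c(0, 0, 0), c(1, -1, 2), c(3, -3, 3))
  s <- gene_reliability(Eb, eps = 1e-6)
  expect_equal(s[1], 1e6)
  expect_equal(gene_reliability(Eb[, 2, drop = FALSE], eps = 1e-12)[1],
               0.25, tolerance = 1e-9)
  expect_true(s[3] < s[2])  # larger l1 noise -> strictly smaller reliability

  wm <- build_weight_matrix(c(0.25, 0.5), K = 2)
  expect_equal(wm$w, c(4, 2))
  expect_equal(wm$W, matrix(c(4, 2, 4, 2), 2, byrow = TRUE))
  expect_equal(nrow(unique(wm$W)), 1L)

  # zero-noise column gets the minimal weight eps
  expect_equal(build_weight_matrix(gene_reliability(
    matrix(0, 5, 1), eps = 1e-6), 3)$w[1], 1e-6)

  # weights are monotone in column noise mass
  set.seed(8)
  En <- matrix(rnorm(30), 6, 5)
  En[, 5] <- En[, 5] * 10
  w <- build_weight_matrix(gene_reliability(En), 2)$w
  ord <- order(colSums(abs(En)))
  expect_equal(order(w), ord)

  expect_error(build_weight_matrix(c(1, -1), 2), "positive")
  expect_error(gene_reliability(Eb, eps = 0), "positive")
})
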