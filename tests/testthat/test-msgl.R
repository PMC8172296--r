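test_that("scores, softmax and likelihood follow their closed forms", {
  expect_equal(class_scores(c(1, 0, -1), matrix(0, 3, 2), c(5, 5)), c(1, 0, -1))
  expect_equal(class_scores(c(0.5, -0.5), matrix(1:4, 2), rep(0, 2)), c(0.5, -0.5))
  expect_equal(class_scores(c(0, 0), rbind(c(1, 0), c(0, 1)), c(2, 3)), c(2, 3))
  expect_error(class_scores(c(0, 0), matrix(0, 2, 3), c(1, 1)), "mismatch")

  expect_equal(softmax_probabilities(c(2, 2, 2)), rep(1 / 3, 3))
  expect_equal(softmax_probabilities(c(0, log(3))), c(0.25, 0.75))
  expect_equal(softmax_probabilities(c(0, log(3)) + 17),
               softmax_probabilities(c(0, log(3))))
  big <- softmax_probabilities(c(1000, 999))
  expect_true(all(is.finite(big)) && abs(sum(big) - 1) < 1e-12)

  Y <- rbind(c(1, 0), c(0, 1))
  expect_equal(multinomial_nll(matrix(0, 2, 2), Y), log(2))
  expect_equal(multinomial_nll(matrix(c(0, log(3)), 1), rbind(c(0, 1))),
               log(4 / 3))
  expect_gte(multinomial_nll(matrix(rnorm(4), 2), Y), 0)
  expect_lt(multinomial_nll(matrix(c(50, 0, 0, 50), 2), Y), 1e-10)
  expect_error(multinomial_nll(matrix(0, 2, 2), rbind(c(1, 1), c(0, 1))),
               "one-hot")
})

test_that("penalty value reduces to its l1 and group endpoints", {
  beta <- matrix(c(3, 4), 1)
  val <- penalty_value(beta, groups = c(1, 1), w = c(1, 2), alpha = 0.5,
                       lambda = 1)
  expect_equal(val, 0.5 * sqrt(2) * 5 + 0.5 * (3 + 8))
  expect_equal(penalty_value(matrix(0, 2, 4), rep(1:2, 2), rep(1, 4), 0.3, 2), 0)
  expect_equal(penalty_value(beta, c(1, 1), c(1, 2), 1, 2), 2 * (3 + 8))
  expect_equal(penalty_value(beta, c(1, 1), c(1, 2), 0, 2), 2 * sqrt(2) * 5)
})

test_that("soft thresholding matches its definition", {
  expect_equal(soft_threshold(3, 2), 1)
  expect_equal(soft_threshold(-3, 2), -1)
  expect_equal(soft_threshold(1, 2), 0)
  z <- c(-2, 0.5, 4)
  expect_equal(soft_threshold(z, 1), c(-1, 0, 3))
})

test_that("the block zero-condition agrees with a generic minimizer", {
  expect_true(group_is_zero(rep(0, 3), 0.5, 1, 3, rep(1, 3)))
  # alpha = 1 endpoint: zero iff every |grad_j| <= lambda * w_j
  g <- c(0.3, -0.8, 0.1); w <- c(1, 2, 1)
  expect_true(group_is_zero(g, 1, 0.5, 3, w))
  expect_false(group_is_zero(c(0.9, 0, 0), 1, 0.5, 3, w))

  # full-problem consistency: at a generic-minimizer solution, blocks the
  # condition declares zero are zero and vice versa
  fx <- make_tiny_fixture(seed = 13)
  alpha <- 0.5
  lam <- 0.08
  sol <- oracle_fista(fx$X, fx$y, fx$groups, fx$w, alpha, lam, n_iter = 20000)
  n <- nrow(fx$X); K <- max(fx$y)
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), fx$y)] <- 1
  for (k in seq_len(K)) {
    for (l in unique(fx$groups)) {
      idx <- which(fx$groups == l)
      beta_z <- sol$beta
      beta_z[k, idx] <- 0
      scores <- sweep(fx$X %*% t(beta_z), 2, sol$beta0, `+`)
      p <- softmax_probabilities(scores)
      grad <- crossprod(fx$X[, idx, drop = FALSE], p[, k] - Y[, k]) / n
      is_zero <- sqrt(sum(sol$beta[k, idx]^2)) <= 1e-6
      expect_equal(group_is_zero(drop(grad), alpha, lam, length(idx), fx$w[idx]),
                   is_zero)
    }
  }
})

test_that("lambda_max returns the top of the path and scales with weights", {
  fx <- make_tiny_fixture(seed = 17)
  Y <- matrix(0, nrow(fx$X), 3); Y[cbind(seq_len(nrow(fx$X)), fx$y)] <- 1
  for (alpha in c(0, 0.5, 1)) {
    lmax <- lambda_max(fx$X, Y, fx$groups, fx$w, alpha)
    fit <- msgl_path(fx$X, fx$y, fx$groups, fx$w, alpha = alpha,
                     lambda = c(lmax, 0.5 * lmax), standardize = FALSE)
    expect_equal(fit$n_nonzero[1], 0L)
    # intercepts at the null fit are log class proportions up to a constant
    prop <- colMeans(Y)
    b0 <- fit$beta0[[1]]
    expect_equal(b0 - mean(b0), log(prop) - mean(log(prop)), tolerance = 1e-4)
    # just below lambda_max at least one block activates
    expect_gte(fit$n_nonzero_groups[2], 1L)
  }
  # alpha = 1 homogeneity: scaling all weights by c scales lambda_max by 1/c
  l1 <- lambda_max(fx$X, Y, fx$groups, fx$w, 1)
  l2 <- lambda_max(fx$X, Y, fx$groups, 3 * fx$w, 1)
  expect_equal(l2, l1 / 3, tolerance = 1e-10)
})

test_that("block coordinate descent matches an independent convex minimizer", {
  fx <- make_tiny_fixture(seed = 11)
  lam <- 0.05
  for (alpha in c(0, 0.5, 1)) {
    fit <- msgl_path(fx$X, fx$y, fx$groups, fx$w, alpha = alpha,
                     lambda = c(2 * lam, lam), standardize = FALSE,
                     tol = 1e-7)
    ours <- oracle_objective(fit$beta0[[2]], fit$beta[[2]], fx$X, fx$y,
                             fx$groups, fx$w, alpha, lam)
    ref <- oracle_fista(fx$X, fx$y, fx$groups, fx$w, alpha, lam,
                        n_iter = 30000)
    theirs <- oracle_objective(ref$beta0, ref$beta, fx$X, fx$y,
                               fx$groups, fx$w, alpha, lam)
    expect_lt(abs(ours - theirs), 1e-6)
    expect_lte(fit$kkt[2], 1e-4)
  }
})

test_that("alpha = 1 with unit weights reproduces l1 multinomial regression", {
  fx <- make_tiny_fixture(seed = 19)
  lam <- 0.04
  fit <- msgl_path(fx$X, fx$y, groups = seq_len(ncol(fx$X)),
                   w = rep(1, ncol(fx$X)), alpha = 1,
                   lambda = c(0.1, lam), standardize = FALSE, tol = 1e-7)
  ref <- oracle_fista(fx$X, fx$y, seq_len(ncol(fx$X)), rep(1, ncol(fx$X)),
                      1, lam, n_iter = 30000)
  ours <- oracle_objective(fit$beta0[[2]], fit$beta[[2]], fx$X, fx$y,
                           seq_len(ncol(fx$X)), rep(1, ncol(fx$X)), 1, lam)
  theirs <- oracle_objective(ref$beta0, ref$beta, fx$X, fx$y,
                             seq_len(ncol(fx$X)), rep(1, ncol(fx$X)), 1, lam)
  expect_lt(abs(ours - theirs), 1e-5)
})

test_that("the lasso endpoint agrees with glmnet's multinomial solver", {
  skip_if_not_installed("glmnet")
  set.seed(42)
  n <- 60; P <- 8; K <- 3
  X <- matrix(rnorm(n * P), n, P)
  b <- matrix(0, K, P); b[1, 1] <- 2; b[2, 2] <- -2
  y <- apply(X %*% t(b) + matrix(rnorm(n * K), n, K), 1, which.max)
  lam <- 0.05
  fit <- msgl_path(X, y, alpha = 1, lambda = c(0.2, 0.1, lam),
                   standardize = FALSE, tol = 1e-7)
  g <- glmnet::glmnet(X, factor(y), family = "multinomial", alpha = 1,
                      lambda = lam, standardize = FALSE, thresh = 1e-12)
  bg <- t(sapply(glmnet::coef.glmnet(g), function(m) as.numeric(m)[-1]))
  b0g <- sapply(glmnet::coef.glmnet(g), function(m) as.numeric(m)[1])
  ours <- oracle_objective(fit$beta0[[3]], fit$beta[[3]], X, y,
                           seq_len(P), rep(1, P), 1, lam)
  theirs <- oracle_objective(b0g, bg, X, y, seq_len(P), rep(1, P), 1, lam)
  expect_lt(abs(ours - theirs), 1e-6)
  expect_lt(max(abs(fit$beta[[3]] - bg)), 1e-3)
})

test_that("path sparsity and weight monotonicity behave as expected", {
  fx <- make_tiny_fixture(seed = 23)
  fit <- msgl_path(fx$X, fx$y, fx$groups, fx$w, alpha = 0.5, nlambda = 20)
  expect_equal(fit$n_nonzero[1], 0L)
  expect_gte(fit$n_nonzero[20], fit$n_nonzero[1])
  expect_true(all(fit$kkt <= 1e-4))
  expect_true(all(is.finite(fit$objective)))
  expect_true(all(diff(fit$lambda) < 0))
  expect_error(msgl_path(fx$X, fx$y, fx$groups, fx$w, lambda = c(1, 2)),
               "decreasing")

  # doubling one weight at alpha = 1 never increases that coefficient
  lam <- 0.05
  f1 <- msgl_path(fx$X, fx$y, groups = seq_len(6), w = rep(1, 6), alpha = 1,
                  lambda = lam, standardize = FALSE, tol = 1e-7)
  w2 <- rep(1, 6); w2[1] <- 2
  f2 <- msgl_path(fx$X, fx$y, groups = seq_len(6), w = w2, alpha = 1,
                  lambda = lam, standardize = FALSE, tol = 1e-7)
  expect_lte(max(abs(f2$beta[[1]][, 1])), max(abs(f1$beta[[1]][, 1])) + 1e-6)
})

test_that("more outer iterations never worsen the objective", {
  fx <- make_tiny_fixture(seed = 29)
  objs <- vapply(c(1, 3, 10, 200), function(mx) {
    msgl_path(fx$X, fx$y, fx$groups, fx$w, alpha = 0.5, lambda = 0.05,
              standardize = FALSE, maxit = mx)$objective[1]
  }, 0)
  expect_true(all(diff(objs) <= 1e-10))
})

test_that("path prediction uses argmax scores with lowest-index ties", {
  fit <- structure(list(
    beta0 = list(log(c(0.5, 0.3, 0.2))), beta = list(matrix(0, 3, 2)),
    lambda = 1), class = "msgl_path")
  pr <- predict(fit, matrix(rnorm(10), 5, 2), s = 1)
  expect_equal(pr$labels, rep(1L, 5))
  expect_equal(pr$probabilities[1, ], c(0.5, 0.3, 0.2))

  tie <- structure(list(beta0 = list(c(0, 0)), beta = list(matrix(0, 2, 2)),
                        lambda = 1), class = "msgl_path")
  expect_equal(predict(tie, matrix(1, 1, 2), s = 1)$labels, 1L)
})
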