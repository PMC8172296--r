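# Independent oracle implementations used only by the tests. These are kept
# deliberately naive (loops, exhaustive enumeration, generic first-order
# optimization) and share no code with the package internals they check.

# naive double-loop responsibility update, damping 0
oracle_responsibility <- function(S, A) {
  n <- nrow(S)
  R <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      others <- setdiff(seq_len(n), k)
      R[i, k] <- S[i, k] - max(A[i, others] + S[i, others])
    }
  }
  R
}

# naive triple-loop availability update, damping 0
oracle_availability <- function(R) {
  n <- nrow(R)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      if (i == k) {
        A[k, k] <- sum(pmax(R[setdiff(seq_len(n), k), k], 0))
      } else {
        others <- setdiff(seq_len(n), c(i, k))
        A[i, k] <- min(0, R[k, k] + sum(pmax(R[others, k], 0)))
      }
    }
  }
  A
}

# net similarity of an exemplar subset: every non-exemplar joins its most
# similar exemplar; exemplars contribute their preferences
oracle_net_similarity <- function(S, exemplars) {
  n <- nrow(S)
  rest <- setdiff(seq_len(n), exemplars)
  sum_sim <- if (length(rest))
    sum(apply(S[rest, exemplars, drop = FALSE], 1, max)) else 0
  sum_sim + sum(diag(S)[exemplars])
}

# best net similarity over all non-empty exemplar subsets (exhaustive)
oracle_best_subset <- function(S) {
  n <- nrow(S)
  best <- -Inf; best_set <- NULL
  for (mask in seq_len(2^n - 1)) {
    ex <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    v <- oracle_net_similarity(S, ex)
    if (v > best) { best <- v; best_set <- ex }
  }
  list(net = best, exemplars = best_set)
}

# full objective of the weighted multinomial sparse group lasso
oracle_objective <- function(beta0, beta, X, y, groups, w, alpha, lambda) {
  n <- nrow(X); K <- max(y)
  scores <- sweep(X %*% t(beta), 2, beta0, `+`)
  lse <- apply(scores, 1, function(r) { m <- max(r); m + log(sum(exp(r - m))) })
  nll <- -mean(scores[cbind(seq_len(n), y)] - lse)
  pen <- 0
  for (k in seq_len(K)) {
    for (l in unique(groups)) {
      b <- beta[k, groups == l]
      pen <- pen + (1 - alpha) * lambda * sqrt(sum(groups == l)) * sqrt(sum(b^2))
    }
    pen <- pen + alpha * lambda * sum(w * abs(beta[k, ]))
  }
  nll + pen
}

# generic accelerated proximal-gradient (FISTA) minimizer of the same
# objective; independent of the package's block coordinate descent
oracle_fista <- function(X, y, groups, w, alpha, lambda, n_iter = 20000) {
  n <- nrow(X); P <- ncol(X); K <- max(y)
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), y)] <- 1
  L <- (0.5 * svd(X, nu = 0, nv = 0)$d[1]^2 / n) + 0.5  # joint (beta, beta0) bound
  th <- matrix(0, K, P + 1)  # column 1 = intercepts
  zee <- th; tk <- 1
  prox <- function(m, step) {
    out <- m
    b <- m[, -1, drop = FALSE]
    b <- sign(b) * pmax(abs(b) - step * alpha * lambda *
                          matrix(w, K, P, byrow = TRUE), 0)
    for (l in unique(groups)) {
      idx <- which(groups == l)
      for (k in seq_len(K)) {
        v <- b[k, idx]
        nv <- sqrt(sum(v^2))
        tau <- step * (1 - alpha) * lambda * sqrt(length(idx))
        b[k, idx] <- if (nv > tau) v * (1 - tau / nv) else 0
      }
    }
    out[, -1] <- b
    out
  }
  grad <- function(m) {
    scores <- sweep(X %*% t(m[, -1, drop = FALSE]), 2, m[, 1], `+`)
    p <- exp(scores - apply(scores, 1, max))
    p <- p / rowSums(p)
    r <- (p - Y) / n
    cbind(colSums(r), t(crossprod(X, r)))
  }
  for (it in seq_len(n_iter)) {
    th_new <- prox(zee - grad(zee) / L, 1 / L)
    tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    zee <- th_new + ((tk - 1) / tk_new) * (th_new - th)
    th <- th_new; tk <- tk_new
  }
  list(beta0 = th[, 1], beta = th[, -1, drop = FALSE])
}

# adjusted Rand index between two partitions
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# small separable multiclass fixture with two planted groups
make_tiny_fixture <- function(seed = 11, n = 30, P = 6, K = 3) {
  set.seed(seed)
  X <- matrix(rnorm(n * P), n, P)
  groups <- rep(1:2, each = P / 2)
  b <- matrix(0, K, P)
  b[1, 1] <- 2.5; b[2, 2] <- -2.5; b[3, 4] <- 2
  y <- apply(X %*% t(b) + 0.3 * matrix(rnorm(n * K), n, K), 1, which.max)
  # ensure all classes present
  y[1:K] <- 1:K
  list(X = X, y = y, groups = groups, w = runif(P, 0.5, 2))
}
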