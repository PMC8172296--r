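#' @useDynLib ramrsgl, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Linear discriminant scores
#'
#' `score_k = beta0[k] + beta[k, ] %*% xbar` for each of the `K` discriminant
#' functions; the predicted class is the argmax of the scores.
#'
#' @param beta0 Length-`K` intercept vector.
#' @param beta `K x P` coefficient matrix.
#' @param xbar Length-`P` vector, or an `n x P` matrix.
#' @return Length-`K` vector (or `n x K` matrix) of scores.
#' @export
class_scores <- function(beta0, beta, xbar) {
  beta <- as.matrix(beta)
  if (is.matrix(xbar)) {
    if (ncol(xbar) != ncol(beta)) stop("dimension mismatch between 'xbar' and 'beta'")
    return(sweep(xbar %*% t(beta), 2, beta0, `+`))
  }
  if (length(xbar) != ncol(beta)) stop("dimension mismatch between 'xbar' and 'beta'")
  drop(beta %*% xbar) + beta0
}

#' Softmax class probabilities
#'
#' Numerically stable (max-shifted) softmax: `p_k = exp(s_k) / sum_j exp(s_j)`.
#' Shifting all scores by a constant leaves the probabilities unchanged.
#'
#' @param scores Length-`K` score vector or `n x K` matrix of scores.
#' @return Probabilities of the same shape, rows summing to 1.
#' @export
softmax_probabilities <- function(scores) {
  if (is.matrix(scores)) {
    sh <- scores - apply(scores, 1, max)
    e <- exp(sh)
    return(e / rowSums(e))
  }
  e <- exp(scores - max(scores))
  e / sum(e)
}

#' Mean multinomial negative log-likelihood
#'
#' `-(1/n) sum_i [score_{i, y_i} - log sum_k exp(score_{i,k})]`, the loss part
#' of the penalized objective.
#'
#' @param scores `n x K` score matrix.
#' @param Y `n x K` one-hot indicator matrix of the observed classes.
#' @return A nonnegative scalar.
#' @export
multinomial_nll <- function(scores, Y) {
  scores <- as.matrix(scores); Y <- as.matrix(Y)
  if (!all(Y %in% c(0, 1)) || any(rowSums(Y) != 1)) stop("'Y' rows must be one-hot")
  m <- apply(scores, 1, max)
  lse <- m + log(rowSums(exp(scores - m)))
  -mean(rowSums(Y * scores) - lse)
}

#' Sparse group lasso penalty value
#'
#' \deqn{(1-\alpha)\lambda \sum_k \sum_l \sqrt{m_l}\,\|\beta^{(k)}_l\|_2
#'   + \alpha\lambda \sum_k \sum_j w_j |\beta^{(k)}_j|.}
#' At `alpha = 1` this is the weighted l1 penalty; at `alpha = 0` the pure
#' group lasso penalty. Groups are blocks of columns within each class row.
#'
#' @param beta `K x P` coefficient matrix.
#' @param groups Integer vector of length `P` mapping columns to groups `1..V`.
#' @param w Positive weight vector of length `P` (l1 term only).
#' @param alpha Mixing parameter in `[0, 1]`.
#' @param lambda Nonnegative penalty level.
#' @return A nonnegative scalar.
#' @export
penalty_value <- function(beta, groups, w, alpha, lambda) {
  beta <- as.matrix(beta)
  groups <- as.integer(groups)
  V <- max(groups)
  sqm <- sqrt(tabulate(groups, V))
  grp_term <- sum(vapply(seq_len(nrow(beta)), function(k) {
    sum(sqm * vapply(seq_len(V), function(l)
      sqrt(sum(beta[k, groups == l]^2)), 0))
  }, 0))
  l1_term <- sum(abs(beta) %*% w)
  (1 - alpha) * lambda * grp_term + alpha * lambda * l1_term
}

#' Scalar soft thresholding
#'
#' `sign(z) * max(|z| - tau, 0)`, the proximal operator of `tau * |.|`.
#' Vectorized over `z` and `tau`.
#'
#' @param z Numeric.
#' @param tau Nonnegative threshold(s).
#' @return Thresholded values.
#' @export
soft_threshold <- function(z, tau) {
  sign(z) * pmax(abs(z) - tau, 0)
}

#' Block optimality condition for a zero group
#'
#' Given the gradient of the (unpenalized) loss with respect to one
#' class-by-group coefficient block, evaluated with that block at zero,
#' decides whether zero is optimal for the block:
#' `||soft_threshold(grad, alpha*lambda*w_block)||_2 <= (1-alpha)*lambda*sqrt(m_l)`.
#'
#' @param grad_block Gradient vector for the block (block set to zero).
#' @param alpha,lambda Penalty parameters.
#' @param m_l Group size (expanded space).
#' @param w_block Weights for the block's columns.
#' @return `TRUE` if the block stays at zero.
#' @export
group_is_zero <- function(grad_block, alpha, lambda, m_l, w_block) {
  st <- soft_threshold(grad_block, alpha * lambda * w_block)
  sqrt(sum(st^2)) <= (1 - alpha) * lambda * sqrt(m_l)
}

one_hot <- function(y, K = max(y)) {
  y <- as.integer(y)
  Y <- matrix(0, length(y), K)
  Y[cbind(seq_along(y), y)] <- 1
  Y
}

# groups must be sorted (block-contiguous); returns 0-based starts and sizes
group_blocks <- function(groups) {
  groups <- as.integer(groups)
  if (is.unsorted(groups)) stop("'groups' must be block-contiguous (sorted)")
  V <- max(groups)
  sizes <- tabulate(groups, V)
  if (any(sizes == 0L)) stop("every group index 1..V must be used")
  starts <- cumsum(c(0L, sizes[-V]))
  list(start = starts, size = sizes, sqm = sqrt(sizes), V = V)
}

#' Smallest penalty level with an all-zero solution
#'
#' Computes `lambda_max`: the smallest `lambda` at which the all-zero
#' coefficient matrix (with intercepts at the null maximum likelihood,
#' i.e. log class proportions) satisfies the block optimality condition for
#' every class-by-group block. The regularization path starts here.
#'
#' @param X `n x P` design (already standardized if desired).
#' @param Y `n x K` one-hot response.
#' @param groups Block-contiguous group index vector, length `P`.
#' @param w Positive l1 weight vector, length `P`.
#' @param alpha Mixing parameter in `[0, 1]`.
#' @return Positive scalar.
#' @export
lambda_max <- function(X, Y, groups, w, alpha) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); K <- ncol(Y)
  pi_k <- colMeans(Y)
  if (any(pi_k == 0)) stop("degenerate response: a class is absent")
  if (K < 2L) stop("at least two classes are required")
  blocks <- group_blocks(groups)
  lmax <- 0
  for (k in seq_len(K)) {
    g_full <- crossprod(X, pi_k[k] - Y[, k]) / n
    for (l in seq_len(blocks$V)) {
      idx <- (blocks$start[l] + 1L):(blocks$start[l] + blocks$size[l])
      g0 <- g_full[idx]
      wl <- w[idx]
      sq <- blocks$sqm[l]
      if (alpha >= 1) {
        lam_l <- max(abs(g0) / wl)
      } else if (alpha <= 0) {
        lam_l <- sqrt(sum(g0^2)) / sq
      } else {
        # smallest lambda with ||S(g0, alpha*lambda*w)|| <= (1-alpha)*lambda*sq;
        # the gap is strictly decreasing in lambda, so bisect
        f <- function(lam) sqrt(sum(soft_threshold(g0, alpha * lam * wl)^2)) -
          (1 - alpha) * lam * sq
        hi <- sqrt(sum(g0^2)) / ((1 - alpha) * sq)
        if (f(hi) > 0) hi <- max(hi, max(abs(g0) / (alpha * wl)))
        lo <- 0
        for (it in 1:100) {
          mid <- (lo + hi) / 2
          if (f(mid) > 0) lo <- mid else hi <- mid
        }
        lam_l <- hi
      }
      lmax <- max(lmax, lam_l)
    }
  }
  lmax
}

#' Fit a weighted multinomial sparse-group-lasso regularization path
#'
#' Fits, for a fixed mixing parameter `alpha`, the penalized multinomial
#' regression
#' \deqn{\min_{\beta_0,\beta}\; \mathrm{NLL}(\beta_0, \beta)
#'  + (1-\alpha)\lambda \sum_{k,l} \sqrt{m_l}\|\beta^{(k)}_l\|_2
#'  + \alpha\lambda \sum_{k,j} w_j |\beta^{(k)}_j|}
#' over a decreasing sequence of `lambda` values with warm starts, by block
#' coordinate descent (outer sweeps; per class-by-group block a subgradient
#' zero-check, then inner proximal-gradient updates combining soft
#' thresholding with group-norm shrinkage under a curvature bound that
#' guarantees the objective never increases). Intercepts are unpenalized.
#'
#' Columns of `X` are standardized to mean 0, variance 1 before fitting by
#' default and the coefficients are transformed back to the original scale.
#'
#' @param X `n x P` numeric design matrix (e.g. an expanded matrix from
#'   [expand_matrix()]).
#' @param y Integer class labels `1..K`, or an `n x K` one-hot matrix.
#' @param groups Block-contiguous group index vector of length `P`; a
#'   `"group_structure"` object is also accepted. Default: one group per
#'   column (lasso-style).
#' @param w Positive l1 weight vector (default all 1).
#' @param alpha Mixing parameter in `[0, 1]`: 1 = weighted lasso, 0 = group
#'   lasso.
#' @param lambda Decreasing sequence of penalty levels, or `NULL` for an
#'   automatic log-spaced path of `nlambda` values from `lambda_max` down to
#'   `lambda_min_ratio * lambda_max`.
#' @param nlambda,lambda_min_ratio Automatic path controls.
#' @param standardize Standardize columns before fitting (default `TRUE`).
#' @param tol Convergence tolerance on the maximum coefficient change.
#' @param maxit Maximum outer iterations per `lambda` value (default 1000).
#' @return Object of class `"msgl_path"`: list with `beta0` (list of
#'   length-`K` vectors), `beta` (list of `K x P` matrices), `lambda`,
#'   `alpha`, `objective`, `kkt`, `n_iter`, `converged`, `n_nonzero`
#'   (coefficients), `n_nonzero_groups`, plus the group/weight metadata.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(60), 20, 3)
#' y <- sample(1:2, 20, replace = TRUE)
#' fit <- msgl_path(X, y, nlambda = 10)
#' fit$n_nonzero
#' @export
msgl_path <- function(X, y, groups = NULL, w = NULL, alpha = 0.5,
                      lambda = NULL, nlambda = 100L, lambda_min_ratio = 1e-3,
                      standardize = TRUE, tol = 1e-5, maxit = 1000L) {
  X <- as.matrix(X)
  n <- nrow(X); P <- ncol(X)
  Y <- if (is.matrix(y) && ncol(y) > 1) as.matrix(y) else one_hot(y)
  K <- ncol(Y)
  if (!all(Y %in% c(0, 1)) || any(rowSums(Y) != 1)) stop("'y' must be one-hot or integer labels")
  if (inherits(groups, "group_structure")) groups <- groups$global_groups
  if (is.null(groups)) groups <- seq_len(P)
  if (length(groups) != P) stop("'groups' must have one entry per column")
  if (is.null(w)) w <- rep(1, P)
  if (length(w) != P || any(w <= 0)) stop("'w' must be positive, one entry per column")
  if (alpha < 0 || alpha > 1) stop("'alpha' must be in [0, 1]")
  blocks <- group_blocks(groups)

  ctr <- rep(0, P); scl <- rep(1, P)
  Xs <- X
  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd) * sqrt((n - 1) / n)
    scl[scl == 0] <- 1
    Xs <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  }

  if (is.null(lambda)) {
    lmax <- lambda_max(Xs, Y, groups, w, alpha)
    lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                      length.out = nlambda))
  } else {
    if (any(diff(lambda) >= 0)) stop("'lambda' must be strictly decreasing")
  }

  pi_k <- colMeans(Y)
  beta0 <- log(pi_k) - mean(log(pi_k))
  beta <- matrix(0, K, P)
  out <- vector("list", length(lambda))
  for (i in seq_along(lambda)) {
    fit <- .msgl_fit_cpp(Xs, Y, blocks$start, blocks$size, blocks$sqm, w,
                         alpha, lambda[i], beta0, beta, tol, as.integer(maxit))
    beta0 <- as.numeric(fit$beta0)
    beta <- fit$beta
    # back-transform to the original column scale
    beta_raw <- sweep(beta, 2, scl, `/`)
    beta0_raw <- beta0 - drop(beta_raw %*% ctr)
    nz_cols <- colSums(beta != 0) > 0
    out[[i]] <- list(beta0 = beta0_raw, beta = beta_raw,
                     objective = fit$objective, kkt = fit$kkt,
                     n_iter = fit$n_iter, converged = fit$converged,
                     n_nonzero = sum(beta != 0),
                     n_nonzero_groups = length(unique(groups[nz_cols])))
  }
  structure(list(
    beta0 = lapply(out, `[[`, "beta0"),
    beta = lapply(out, `[[`, "beta"),
    lambda = lambda, alpha = alpha,
    objective = vapply(out, `[[`, 0, "objective"),
    kkt = vapply(out, `[[`, 0, "kkt"),
    n_iter = vapply(out, `[[`, 0L, "n_iter"),
    converged = vapply(out, `[[`, TRUE, "converged"),
    n_nonzero = vapply(out, `[[`, 0L, "n_nonzero"),
    n_nonzero_groups = vapply(out, `[[`, 0L, "n_nonzero_groups"),
    groups = as.integer(groups), w = w, K = K, P = P,
    standardize = standardize, center = ctr, scale = scl
  ), class = "msgl_path")
}

#' @export
print.msgl_path <- function(x, ...) {
  cat(sprintf("Multinomial sparse group lasso path: alpha = %g, %d lambda values\n",
              x$alpha, length(x$lambda)))
  cat(sprintf("  K = %d classes, P = %d columns, %d groups\n",
              x$K, x$P, max(x$groups)))
  df <- data.frame(lambda = signif(x$lambda, 4), nonzero = x$n_nonzero,
                   groups = x$n_nonzero_groups, objective = signif(x$objective, 6))
  idx <- unique(round(seq(1, nrow(df), length.out = min(10, nrow(df)))))
  print(df[idx, ], row.names = FALSE)
  invisible(x)
}

#' Predict classes and probabilities from a fitted path
#'
#' @param object An `"msgl_path"` fit.
#' @param newx Matrix of new samples in the same column space the path was
#'   fitted on.
#' @param s Index into the lambda sequence (default: last, smallest lambda).
#' @param ... Unused.
#' @return List with `labels` (argmax of the scores; exact ties go to the
#'   lowest class index) and `probabilities` (`n x K`).
#' @export
predict.msgl_path <- function(object, newx, s = length(object$lambda), ...) {
  newx <- as.matrix(newx)
  scores <- class_scores(object$beta0[[s]], object$beta[[s]], newx)
  if (!is.matrix(scores)) scores <- matrix(scores, nrow = 1)
  labels <- apply(scores, 1, which.max)  # first max = lowest class index on ties
  list(labels = as.integer(labels), probabilities = softmax_probabilities(scores))
}

#' @importFrom graphics matplot abline legend
#' @export
plot.msgl_path <- function(x, ...) {
  B <- t(vapply(seq_along(x$lambda),
                function(i) as.numeric(x$beta[[i]]), numeric(x$K * x$P)))
  matplot(log(x$lambda), B, type = "l", lty = 1,
          xlab = expression(log(lambda)), ylab = "coefficient",
          main = sprintf("Coefficient paths (alpha = %g)", x$alpha), ...)
  invisible(x)
}
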