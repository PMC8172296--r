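#' Negative squared Euclidean similarity matrix
#'
#' Builds the affinity-propagation input similarity
#' \eqn{s(i,k) = -\|x_i - x_k\|^2} for all pairs of rows of `points`. The
#' diagonal (the preferences) is left as `NA`; fill it with
#' [set_preference()].
#'
#' @param points Numeric matrix, one point per row.
#' @return An n-by-n symmetric matrix with `NA` diagonal.
#' @export
similarity_matrix <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) == 0L) stop("'points' must contain at least one row")
  if (!all(is.finite(points))) stop("'points' must have finite entries")
  d2 <- as.matrix(stats::dist(points))^2
  S <- -d2
  diag(S) <- NA_real_
  S
}

#' Set affinity-propagation preferences
#'
#' Sets every diagonal entry of a similarity matrix to a common preference
#' value `p`. The preference is the self-similarity controlling how readily a
#' point becomes an exemplar: larger values yield more clusters. `"median"`
#' (the canonical default) uses the median of all off-diagonal similarities.
#'
#' @param S Square similarity matrix (diagonal ignored/overwritten).
#' @param p A single number, or `"median"`.
#' @return `S` with the diagonal set.
#' @export
set_preference <- function(S, p = "median") {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S)) stop("'S' must be square")
  if (identical(p, "median")) {
    off <- S[row(S) != col(S)]
    p <- if (length(off)) stats::median(off) else 0
  }
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p)) {
    stop("'p' must be a single finite number or \"median\"")
  }
  diag(S) <- p
  S
}

# One damped responsibility update:
#   r(i,k) <- s(i,k) - max_{k' != k} (a(i,k') + s(i,k'))
update_responsibility <- function(S, R, A, damping = 0) {
  AS <- A + S
  n <- nrow(S)
  # row-wise largest and second largest of AS
  top_idx <- max.col(AS, ties.method = "first")
  top_val <- AS[cbind(seq_len(n), top_idx)]
  AS2 <- AS
  AS2[cbind(seq_len(n), top_idx)] <- -Inf
  second_val <- AS2[cbind(seq_len(n), max.col(AS2, ties.method = "first"))]
  Rnew <- S - top_val           # subtract row max everywhere ...
  fix <- cbind(seq_len(n), top_idx)
  Rnew[fix] <- S[fix] - second_val  # ... except at the argmax, which excludes itself
  damping * R + (1 - damping) * Rnew
}

# One damped availability update:
#   a(i,k) <- min(0, r(k,k) + sum_{i' not in {i,k}} max(0, r(i',k)))  for i != k
#   a(k,k) <- sum_{i' != k} max(0, r(i',k))
update_availability <- function(R, A, damping = 0) {
  n <- nrow(R)
  Rp <- pmax(R, 0)
  diag(Rp) <- 0                       # exclude i' = k from the positive sums
  colsum <- colSums(Rp)
  Anew <- rep(diag(R) + colsum, each = n) - Rp  # excludes i' = i
  Anew <- pmin(Anew, 0)
  diag(Anew) <- colsum
  damping * A + (1 - damping) * Anew
}

#' Affinity propagation clustering
#'
#' Exemplar-based clustering by responsibility/availability message passing.
#' Points exchange two kinds of messages: the responsibility `r(i,k)`, the
#' accumulated evidence that point `k` should serve as the exemplar for point
#' `i`, and the availability `a(i,k)`, the accumulated evidence that point `i`
#' should pick `k` as its exemplar. After convergence, the exemplars are the
#' points with `a(k,k) + r(k,k) > 0`, and every other point joins the exemplar
#' it is most similar to. The number of clusters is not fixed in advance; it
#' emerges from the preferences on the diagonal of `S`.
#'
#' Convergence is declared when the exemplar set is unchanged for `conv_iter`
#' consecutive iterations. The update is deterministic for a given `S`; no
#' random jitter is added (set `jitter` to a small positive value, with
#' `seed`, to break exact symmetric ties the way the canonical implementation
#' does). Ties in the label assignment go to the lowest index.
#'
#' @param S Square similarity matrix with finite entries, preferences on the
#'   diagonal (see [set_preference()]).
#' @param damping Damping factor in `[0, 1)` applied to both message updates.
#' @param max_iter Maximum number of message-passing iterations.
#' @param conv_iter Number of consecutive iterations with an unchanged
#'   exemplar set required to declare convergence.
#' @param jitter If positive, adds uniform noise of this amplitude to `S`.
#' @param seed Seed for the jitter draw (ignored when `jitter = 0`).
#' @return An object of class `"ap_result"`: list with `exemplars` (integer
#'   indices), `labels` (per-point exemplar index), `n_iter`, `converged`,
#'   `sum_of_similarities` (sum of `s(i, exemplar(i))` over non-exemplars) and
#'   `net_similarity` (that sum plus the preferences of the exemplars).
#' @examples
#' pts <- matrix(c(0, 0.1, 100, 100.1), ncol = 1)
#' S <- set_preference(similarity_matrix(pts), "median")
#' ap_cluster(S)$exemplars
#' @export
ap_cluster <- function(S, damping = 0.9, max_iter = 1000L, conv_iter = 100L,
                       jitter = 0, seed = 1L) {
  S <- as.matrix(S)
  n <- nrow(S)
  if (n != ncol(S)) stop("'S' must be square")
  if (!all(is.finite(S))) stop("'S' must have finite entries (set the preferences first)")
  if (damping < 0 || damping >= 1) stop("'damping' must be in [0, 1)")
  if (n == 1L) {
    return(structure(list(exemplars = 1L, labels = 1L, n_iter = 0L,
                          converged = TRUE, sum_of_similarities = 0,
                          net_similarity = S[1, 1]), class = "ap_result"))
  }
  if (jitter > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    S <- S + matrix(stats::runif(n * n, -jitter, jitter), n, n)
  }
  R <- matrix(0, n, n)
  A <- matrix(0, n, n)
  exemplars <- integer(0)
  stable <- 0L
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    R <- update_responsibility(S, R, A, damping)
    A <- update_availability(R, A, damping)
    ex <- which(diag(A) + diag(R) > 0)
    if (length(ex) && identical(ex, exemplars)) {
      stable <- stable + 1L
      if (stable >= conv_iter) {
        converged <- TRUE
        break
      }
    } else {
      stable <- 0L
    }
    exemplars <- ex
  }
  if (length(exemplars) == 0L) {
    # degenerate: no point accumulated positive evidence; fall back to the
    # best single exemplar and flag non-convergence
    exemplars <- which.max(diag(A) + diag(R))
    converged <- FALSE
  }
  labels <- exemplars[max.col(S[, exemplars, drop = FALSE], ties.method = "first")]
  labels[exemplars] <- exemplars
  sum_sim <- sum(S[cbind(seq_len(n), labels)][-exemplars])
  if (length(exemplars) == n) sum_sim <- 0
  net <- sum_sim + sum(diag(S)[exemplars])
  structure(list(exemplars = as.integer(exemplars), labels = as.integer(labels),
                 n_iter = iter, converged = converged,
                 sum_of_similarities = sum_sim, net_similarity = net),
            class = "ap_result")
}

#' @export
print.ap_result <- function(x, ...) {
  cat(sprintf("Affinity propagation: %d clusters from %d points\n",
              length(x$exemplars), length(x$labels)))
  cat(sprintf("  exemplars: %s\n", paste(x$exemplars, collapse = ", ")))
  cat(sprintf("  iterations: %d   converged: %s\n", x$n_iter, x$converged))
  cat(sprintf("  sum of similarities: %.4f   net similarity: %.4f\n",
              x$sum_of_similarities, x$net_similarity))
  invisible(x)
}
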