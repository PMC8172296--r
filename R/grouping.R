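#' Cluster genes within each class
#'
#' Runs affinity propagation on the genes of each class separately, on the
#' clean (noise-removed) matrix. For class `t`, the class-`t` rows of `D` are
#' taken, each gene profile is z-scored across those samples, and genes are
#' clustered on negative squared Euclidean distance — for z-scored profiles a
#' monotone affine function of the Pearson correlation between the original
#' profiles, so correlation-similar genes land in the same group. Genes with
#' zero variance within a class are mapped to the zero profile (not `NaN`) so
#' the clustering stays defined.
#'
#' @param D Numeric samples-by-genes matrix (typically the clean part from
#'   [rpca()]).
#' @param y Integer class labels in `1..K`, one per row of `D`.
#' @param preference Common preference passed to [set_preference()]; default
#'   `"median"`.
#' @param damping,max_iter,conv_iter Passed to [ap_cluster()].
#' @param jitter,seed Amplitude and seed of the similarity jitter passed to
#'   [ap_cluster()]. Z-scored gene profiles are frequently exact duplicates
#'   (perfectly correlated genes), and exactly tied similarities make the
#'   message passing collapse; a tiny fixed-seed jitter breaks the ties while
#'   keeping the clustering deterministic. Set `jitter = 0` to disable.
#' @return A list of `K` integer vectors of length `ncol(D)`; vector `t` maps
#'   each gene to its within-class group, numbered `1..n_groups(t)` in order
#'   of first appearance.
#' @export
cluster_per_class <- function(D, y, preference = "median", damping = 0.9,
                              max_iter = 1000L, conv_iter = 100L,
                              jitter = 1e-6, seed = 1L) {
  D <- as.matrix(D)
  y <- as.integer(y)
  if (length(y) != nrow(D)) stop("'y' must have one label per row of 'D'")
  K <- max(y)
  if (any(tabulate(y, K) < 2L)) stop("every class needs at least 2 samples to cluster its genes")
  pref <- preference
  lapply(seq_len(K), function(t) {
    Z <- D[y == t, , drop = FALSE]
    Z <- scale(Z)                       # z-score each gene across class-t samples
    Z[!is.finite(Z)] <- 0               # zero-variance genes -> zero profile
    S <- similarity_matrix(t(Z))
    off <- S[row(S) != col(S)]
    S <- set_preference(S, pref)
    # jitter is relative to the similarity spread; a fully degenerate class
    # (all profiles identical) gets none and collapses to one cluster
    res <- ap_cluster(S, damping = damping, max_iter = max_iter,
                      conv_iter = conv_iter,
                      jitter = jitter * diff(range(off)), seed = seed)
    renumber_first_appearance(res$labels)
  })
}

renumber_first_appearance <- function(labels) {
  as.integer(match(labels, unique(labels)))
}

#' Overlap expansion of a samples-by-genes matrix
#'
#' Duplicates the `M` gene columns of `A` once per class so that each class's
#' own clustering defines a block of groups: for class `t` the columns are
#' stably reordered so genes of group 1 come first, then group 2, and so on
#' (genes keep their original relative order within a group), and the `K`
#' reordered copies are concatenated left to right. The result has `K * M`
#' columns with block-contiguous groups, numbered globally `1..V` across
#' classes in class order.
#'
#' @param A Numeric matrix with `M` columns.
#' @param indicators List of `K` integer vectors of length `M` (one per
#'   class), as returned by [cluster_per_class()].
#' @return A list with `matrix` (the `n x K*M` expanded matrix) and `groups`,
#'   a `"group_structure"` object: list with `per_class_indicators`,
#'   `global_groups` (length `K*M`), `V` (total group count), `group_sizes`,
#'   `column_map` (data frame: `column`, `class`, `gene`, `group`), `K`, `M`.
#' @examples
#' A <- matrix(1:4, nrow = 1)
#' ex <- expand_matrix(matrix(c(1, 2), 1), list(c(1L, 1L), c(1L, 2L)))
#' ex$groups$V  # 3 groups
#' @export
expand_matrix <- function(A, indicators) {
  A <- as.matrix(A)
  M <- ncol(A)
  if (!length(indicators)) stop("'indicators' must be a non-empty list")
  if (any(vapply(indicators, length, 1L) != M)) {
    stop("each indicator vector must have length ncol(A)")
  }
  K <- length(indicators)
  cols <- integer(0)
  cls <- integer(0)
  grp <- integer(0)
  offset <- 0L
  for (t in seq_len(K)) {
    v <- as.integer(indicators[[t]])
    ord <- order(v, seq_len(M))          # stable: group, then original index
    cols <- c(cols, ord)
    cls <- c(cls, rep(t, M))
    grp <- c(grp, v[ord] + offset)
    offset <- offset + max(v)
  }
  V <- offset
  gs <- structure(list(
    per_class_indicators = lapply(indicators, as.integer),
    global_groups = grp,
    V = as.integer(V),
    group_sizes = tabulate(grp, V),
    column_map = data.frame(column = seq_len(K * M), class = cls,
                            gene = cols, group = grp),
    K = as.integer(K), M = as.integer(M)
  ), class = "group_structure")
  Abar <- A[, cols, drop = FALSE]
  if (!is.null(colnames(A))) {
    colnames(Abar) <- paste0(colnames(A)[cols], ".c", cls)
  }
  list(matrix = Abar, groups = gs)
}

#' @export
print.group_structure <- function(x, ...) {
  cat(sprintf("Overlap group structure: %d classes x %d genes -> %d columns in %d groups\n",
              x$K, x$M, x$K * x$M, x$V))
  per <- vapply(x$per_class_indicators, max, 1L)
  cat(sprintf("  groups per class: %s\n", paste(per, collapse = ", ")))
  cat(sprintf("  group sizes: min %d, median %g, max %d\n",
              min(x$group_sizes), stats::median(x$group_sizes), max(x$group_sizes)))
  invisible(x)
}

#' Expand a new sample (or matrix of samples) to the overlap design
#'
#' Maps vectors in the original `M`-gene space into the `K*M`-column expanded
#' space of a [expand_matrix()] group structure, so that test samples match
#' the training design: `xbar[j] = x[gene(j)]`.
#'
#' @param x Numeric vector of length `M`, or a matrix with `M` columns.
#' @param gs A `"group_structure"` object.
#' @return A vector of length `K*M`, or a matrix with `K*M` columns.
#' @export
apply_expansion <- function(x, gs) {
  stopifnot(inherits(gs, "group_structure"))
  if (is.matrix(x)) {
    if (ncol(x) != gs$M) stop("'x' must have M = ", gs$M, " columns")
    return(x[, gs$column_map$gene, drop = FALSE])
  }
  if (length(x) != gs$M) stop("'x' must have length M = ", gs$M)
  x[gs$column_map$gene]
}

#' Gene reliability from the expanded noise matrix
#'
#' The reliability of expanded column `j` is the reciprocal noise mass
#' `s[j] = 1 / (||Ebar[, j]||_1 + eps)`: the noisier a gene, the less reliable
#' it is and the smaller its `s`.
#'
#' @param E_bar Expanded noise matrix (`n x K*M`).
#' @param eps Small positive stabilizer (default `1e-6`).
#' @return Numeric vector of per-column reliabilities.
#' @export
gene_reliability <- function(E_bar, eps = 1e-6) {
  if (eps <= 0) stop("'eps' must be positive")
  1 / (colSums(abs(as.matrix(E_bar))) + eps)
}

#' Adaptive penalty weights from gene reliabilities
#'
#' The penalty weight of a gene is the reciprocal of its reliability,
#' `w = 1/s` (so `w[j]` equals the l1 noise mass of column `j` plus `eps`):
#' noisier genes are penalized more. Because the coefficients of the same
#' gene in every discriminant function share the weight, the weight vector is
#' replicated as the `K` identical rows of the weight matrix `W`.
#'
#' @param s Positive reliability vector from [gene_reliability()].
#' @param K Number of classes.
#' @param normalize If `TRUE`, rescales `w` to mean 1, decoupling the scale
#'   of the penalty parameter from the absolute noise magnitude. Default
#'   `FALSE` (weights used as-is).
#' @return List with `w` (length `K*M`) and `W` (`K` identical rows).
#' @export
build_weight_matrix <- function(s, K, normalize = FALSE) {
  if (any(!is.finite(s)) || any(s <= 0)) stop("'s' must be positive and finite")
  w <- 1 / s
  if (normalize) w <- w / mean(w)
  list(w = w, W = matrix(w, nrow = K, ncol = length(w), byrow = TRUE))
}
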