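#' Stratified train/test split
#'
#' Splits samples into a training and test set class by class: per class,
#' `round(n_class * train_fraction)` samples (nearest integer, halves away
#' from zero) are drawn uniformly without replacement into the training set,
#' and the remainder go to the test set. Deterministic for a fixed seed.
#'
#' @param y Class labels (integer `1..K`, factor, or character).
#' @param train_fraction Fraction of each class used for training, in (0, 1);
#'   default 2/3.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @examples
#' sp <- stratified_split(rep(1:3, c(38, 9, 25)), 2/3, seed = 1)
#' table(rep(1:3, c(38, 9, 25))[sp$train])  # 25, 6, 17
#' @export
stratified_split <- function(y, train_fraction = 2/3, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) stop("'train_fraction' must be in (0, 1)")
  yi <- encode_labels(y)$y
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  train <- integer(0)
  for (k in sort(unique(yi))) {
    idx <- which(yi == k)
    n_tr <- floor(length(idx) * train_fraction + 0.5)  # round half away from zero
    if (n_tr == 0L) stop("class ", k, " would have no training samples")
    train <- c(train, sort(sample(idx, n_tr)))
  }
  train <- sort(train)
  test <- setdiff(seq_along(yi), train)
  if (length(test) == 0L) stop("the test set is empty; lower 'train_fraction'")
  list(train = train, test = test)
}

encode_labels <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    levels <- unique(y)
    return(list(y = match(y, levels), levels = levels))
  }
  y <- as.integer(y)
  if (any(is.na(y)) || any(y < 1)) stop("integer labels must be in 1..K")
  list(y = y, levels = as.character(seq_len(max(y))))
}

#' Baseline and full model configurations
#'
#' Returns the configuration of the full RAMRSGL pipeline or of one of the
#' baseline models it is compared against:
#'
#' * `"RAMRSGL"` — RPCA decomposition, per-class AP grouping with overlap
#'   expansion, noise-driven adaptive weights, alpha grid.
#' * `"MRSGL"` — same grouping/expansion but unit weights; raw input by
#'   default (`on_clean = TRUE` runs it on the RPCA-cleaned matrix).
#' * `"MRGL"` — group lasso only (`alpha = 0`), unit weights.
#' * `"L1"` — plain l1 multinomial regression (`alpha = 1`, unit weights, no
#'   clustering/expansion, singleton groups on the raw columns).
#'
#' `"AMRSGL"` (WGCNA-based grouping) is not supported and raises an error.
#'
#' @param name One of `"RAMRSGL"`, `"MRSGL"`, `"MRGL"`, `"L1"`.
#' @param on_clean Run a baseline on the RPCA-cleaned matrix instead of the
#'   raw one (ignored for `"RAMRSGL"`, which always decomposes).
#' @param alpha Override the alpha grid.
#' @param nlambda,lambda_min_ratio,nfolds,preference,damping,eps,maxit,tol
#'   Tuning controls; see [ramrsgl()].
#' @param cv_tol Solver tolerance used inside the cross-validation loop
#'   (looser than `tol`, which governs the final refit; accuracy-based model
#'   selection does not need fully polished coefficients).
#' @param normalize_weights Rescale adaptive weights to mean 1 (see
#'   [build_weight_matrix()]).
#' @return A named configuration list of class `"ramrsgl_config"`.
#' @export
baseline_config <- function(name = c("RAMRSGL", "MRSGL", "MRGL", "L1", "AMRSGL"),
                            on_clean = FALSE, alpha = NULL,
                            nlambda = 100L, lambda_min_ratio = 1e-3,
                            nfolds = 5L, preference = "median", damping = 0.9,
                            eps = 1e-6, normalize_weights = FALSE,
                            maxit = 1000L, tol = 1e-5, cv_tol = 1e-3) {
  name <- match.arg(name)
  if (name == "AMRSGL") {
    stop("AMRSGL (WGCNA-based grouping) is not supported by this package")
  }
  cfg <- list(
    name = name,
    use_rpca = name == "RAMRSGL" || on_clean,
    grouping = if (name == "L1") "none" else "ap",
    adaptive_weights = name == "RAMRSGL",
    alpha = if (!is.null(alpha)) alpha else switch(name,
      RAMRSGL = c(0.1, 0.25, 0.5, 0.75, 0.9),
      MRSGL = c(0.1, 0.25, 0.5, 0.75, 0.9),
      MRGL = 0, L1 = 1),
    nlambda = nlambda, lambda_min_ratio = lambda_min_ratio, nfolds = nfolds,
    preference = preference, damping = damping, eps = eps,
    normalize_weights = normalize_weights, maxit = maxit, tol = tol,
    cv_tol = cv_tol
  )
  class(cfg) <- "ramrsgl_config"
  cfg
}

#' Fit the RAMRSGL model
#'
#' End-to-end fit of robust adaptive multinomial regression with sparse group
#' lasso on a training set:
#'
#' 1. the expression matrix is decomposed by [rpca()] into a clean low-rank
#'    part `D` and a sparse noise part `E`;
#' 2. genes are clustered within each class on `D` by affinity propagation
#'    ([cluster_per_class()]);
#' 3. `D` and `E` are overlap-expanded to `K * M` columns
#'    ([expand_matrix()]), so each class contributes its own group structure;
#' 4. adaptive penalty weights are built from the l1 noise mass of the
#'    expanded noise columns ([gene_reliability()], [build_weight_matrix()]);
#' 5. a weighted multinomial sparse-group-lasso path ([msgl_path()]) is
#'    fitted for each alpha in the grid, and `(alpha, lambda)` are chosen by
#'    stratified `nfolds`-fold cross-validated accuracy (ties prefer the
#'    sparser model: larger lambda, then smaller alpha);
#' 6. the model at the chosen `(alpha, lambda)` refitted on the full training
#'    set is returned, with the selected genes mapped back to the original
#'    gene identifiers (expanded copies deduplicated).
#'
#' Baselines drop individual stages; see [baseline_config()].
#'
#' @param x Numeric samples-by-genes training matrix.
#' @param y Class labels (integer `1..K`, factor, or character), one per row.
#' @param config A configuration from [baseline_config()]; default the full
#'   `"RAMRSGL"` pipeline.
#' @param seed Integer seed controlling the cross-validation fold assignment.
#' @return An object of class `"ramrsgl"`; see Details. Methods: `print`,
#'   `summary`, `coef`, `predict`, `plot`, `fitted`, `residuals`.
#' @details The returned fit contains `coefficients` (`K x K*M`),
#'   `intercepts`, `alpha`, `lambda`, `cv` (per-alpha matrices of fold-mean
#'   CV accuracy along the path), `groups` (the `"group_structure"`),
#'   `weights`, `rpca` (rank, noise share, convergence), `selected_genes`,
#'   `selected_groups` (data frame of active (class row, group) blocks),
#'   `levels` (class labels), and the training data dimensions.
#' @examples
#' sim <- simulate_expression(n_per_class = 10, n_genes = 40, seed = 1)
#' cfg <- baseline_config("RAMRSGL", nlambda = 20, nfolds = 3)
#' fit <- ramrsgl(sim$dataset$X, sim$dataset$y, config = cfg, seed = 1)
#' fit$selected_genes
#' @export
ramrsgl <- function(x, y, config = baseline_config("RAMRSGL"), seed = 1L) {
  x <- as.matrix(x)
  enc <- encode_labels(y)
  yi <- enc$y
  K <- max(yi)
  if (length(yi) != nrow(x)) stop("'y' must have one label per row of 'x'")
  if (K < 2L) stop("at least two classes are required")
  if (is.null(colnames(x))) colnames(x) <- sprintf("gene_%d", seq_len(ncol(x)))
  gene_ids <- colnames(x)
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers")

  # stage 1: robust decomposition
  if (config$use_rpca) {
    rp <- rpca(x)
    D <- rp$D; E <- rp$E
    rpca_info <- list(rank_D = rp$rank_D, noise_share = mean(rp$E != 0),
                      converged = rp$converged, lam = rp$lam)
  } else {
    D <- x; E <- matrix(0, nrow(x), ncol(x))
    rpca_info <- NULL
  }

  # stages 2-3: per-class grouping and overlap expansion
  if (config$grouping == "ap") {
    indicators <- cluster_per_class(D, yi, preference = config$preference,
                                    damping = config$damping)
  } else {
    indicators <- list(seq_len(ncol(x)))  # singleton groups, no duplication
  }
  design_src <- if (config$use_rpca) D else x
  ex <- expand_matrix(design_src, indicators)
  Xbar <- ex$matrix
  gs <- ex$groups

  # stage 4: adaptive weights from the expanded noise matrix
  if (config$adaptive_weights) {
    Ebar <- apply_expansion(E, gs)
    s <- gene_reliability(Ebar, eps = config$eps)
    w <- build_weight_matrix(s, K, normalize = config$normalize_weights)$w
  } else {
    w <- rep(1, ncol(Xbar))
  }

  # stage 5: cross-validated (alpha, lambda) selection
  alphas <- config$alpha
  folds <- stratified_folds(yi, config$nfolds, seed)
  cv <- vector("list", length(alphas))
  lambdas <- vector("list", length(alphas))
  for (a in seq_along(alphas)) {
    full_path_lambda <- msgl_lambda_grid(Xbar, yi, gs, w, alphas[a],
                                         config$nlambda, config$lambda_min_ratio)
    acc <- matrix(NA_real_, length(full_path_lambda), max(folds))
    for (f in seq_len(max(folds))) {
      tr <- folds != f
      fit_f <- msgl_path(Xbar[tr, , drop = FALSE], yi[tr], gs, w,
                         alpha = alphas[a], lambda = full_path_lambda,
                         tol = config$cv_tol, maxit = config$maxit)
      for (i in seq_along(full_path_lambda)) {
        pr <- predict(fit_f, Xbar[!tr, , drop = FALSE], s = i)
        acc[i, f] <- mean(pr$labels == yi[!tr])
      }
    }
    cv[[a]] <- rowMeans(acc)
    lambdas[[a]] <- full_path_lambda
  }
  # argmax of CV accuracy; ties -> larger lambda (smaller path index), then
  # smaller alpha
  best <- c(1L, 1L); best_acc <- -Inf
  for (a in seq_along(alphas)) {
    for (i in seq_along(lambdas[[a]])) {
      if (cv[[a]][i] > best_acc + 1e-12) {
        best_acc <- cv[[a]][i]; best <- c(a, i)
      }
    }
  }
  a_star <- best[1L]; i_star <- best[2L]

  # stage 6: refit on the full training data at the chosen (alpha, lambda)
  path <- msgl_path(Xbar, yi, gs, w, alpha = alphas[a_star],
                    lambda = lambdas[[a_star]][seq_len(i_star)],
                    tol = config$tol, maxit = config$maxit)
  beta <- path$beta[[i_star]]
  beta0 <- path$beta0[[i_star]]

  nz_col <- which(colSums(beta != 0) > 0)
  selected_genes <- sort(unique(gene_ids[gs$column_map$gene[nz_col]]))
  nz <- which(beta != 0, arr.ind = TRUE)
  sel_blocks <- unique(data.frame(class_row = nz[, 1],
                                  group = gs$column_map$group[nz[, 2]]))
  sel_blocks <- sel_blocks[order(sel_blocks$class_row, sel_blocks$group), ]
  rownames(sel_blocks) <- NULL

  fit <- structure(list(
    coefficients = beta, intercepts = beta0,
    alpha = alphas[a_star], lambda = lambdas[[a_star]][i_star],
    cv_accuracy = best_acc,
    cv = mapply(function(l, a) data.frame(lambda = l, accuracy = a),
                lambdas, cv, SIMPLIFY = FALSE),
    alphas = alphas,
    path = path, groups = gs, weights = w, rpca = rpca_info,
    selected_genes = selected_genes, selected_groups = sel_blocks,
    levels = enc$levels, gene_ids = gene_ids, K = K,
    n = nrow(x), M = ncol(x), config = config, seed = seed,
    y = yi, x_train = x
  ), class = "ramrsgl")
  fit
}

stratified_folds <- function(y, nfolds, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  folds <- integer(length(y))
  for (k in unique(y)) {
    idx <- sample(which(y == k))
    folds[idx] <- rep_len(seq_len(nfolds), length(idx))
  }
  folds
}

msgl_lambda_grid <- function(Xbar, y, gs, w, alpha, nlambda, lambda_min_ratio) {
  n <- nrow(Xbar)
  ctr <- colMeans(Xbar)
  scl <- apply(Xbar, 2, stats::sd) * sqrt((n - 1) / n)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(Xbar, 2, ctr), 2, scl, `/`)
  lmax <- lambda_max(Xs, one_hot(y), gs$global_groups, w, alpha)
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
}

#' @export
print.ramrsgl <- function(x, ...) {
  cat(sprintf("RAMRSGL fit (%s): %d samples x %d genes, %d classes\n",
              x$config$name, x$n, x$M, x$K))
  if (!is.null(x$rpca)) {
    cat(sprintf("  RPCA: rank(D) = %d, %.1f%% noisy entries\n",
                x$rpca$rank_D, 100 * x$rpca$noise_share))
  }
  cat(sprintf("  groups: %d (expanded design: %d columns)\n",
              x$groups$V, x$groups$K * x$groups$M))
  cat(sprintf("  chosen alpha = %g, lambda = %.5g (CV accuracy %.3f)\n",
              x$alpha, x$lambda, x$cv_accuracy))
  cat(sprintf("  selected genes: %d\n", length(x$selected_genes)))
  invisible(x)
}

#' @export
summary.ramrsgl <- function(object, ...) {
  print(object)
  cat("\nActive (class row, group) blocks:\n")
  print(object$selected_groups, row.names = FALSE)
  cat("\nSelected genes:\n")
  print(object$selected_genes)
  invisible(object)
}

#' @export
coef.ramrsgl <- function(object, ...) {
  out <- cbind(`(Intercept)` = object$intercepts, object$coefficients)
  rownames(out) <- object$levels
  out
}

#' Predict classes for new samples
#'
#' New samples are given in the original `M`-gene space and expanded
#' internally through the training group structure (raw values: the training
#' decomposition is not applied to new data). Ties in the discriminant scores
#' go to the lowest class index.
#'
#' @param object A `"ramrsgl"` fit.
#' @param newx Matrix with the training genes as columns (or a single vector).
#' @param ... Unused.
#' @return List with `labels` (in the original label coding),
#'   `class_index` (integer `1..K`) and `probabilities`.
#' @export
predict.ramrsgl <- function(object, newx, ...) {
  if (!is.matrix(newx)) newx <- matrix(newx, nrow = 1)
  if (ncol(newx) != object$M) stop("'newx' must have ", object$M, " columns")
  xbar <- apply_expansion(newx, object$groups)
  scores <- class_scores(object$intercepts, object$coefficients, xbar)
  if (!is.matrix(scores)) scores <- matrix(scores, nrow = 1)
  idx <- apply(scores, 1, which.max)
  list(labels = object$levels[idx], class_index = as.integer(idx),
       probabilities = softmax_probabilities(scores))
}

#' @export
fitted.ramrsgl <- function(object, ...) {
  predict(object, object$x_train)$probabilities
}

#' @export
residuals.ramrsgl <- function(object, ...) {
  one_hot(object$y, object$K) - fitted(object)
}

#' @importFrom graphics lines
#' @export
plot.ramrsgl <- function(x, ...) {
  cols <- seq_along(x$alphas)
  rng <- range(unlist(lapply(x$cv, function(d) d$accuracy)))
  plot(NA, xlim = rev(range(log(unlist(lapply(x$cv, function(d) d$lambda))))),
       ylim = rng, xlab = expression(log(lambda)), ylab = "CV accuracy",
       main = "Cross-validated accuracy along the path", ...)
  for (a in cols) {
    lines(log(x$cv[[a]]$lambda), x$cv[[a]]$accuracy, col = a)
  }
  abline(v = log(x$lambda), lty = 2)
  legend("bottomleft", legend = paste("alpha =", x$alphas), col = cols,
         lty = 1, bty = "n")
  invisible(x)
}

#' Split, fit and evaluate once
#'
#' Runs one complete experiment: stratified split of the dataset, RAMRSGL (or
#' baseline) fit on the training part, and evaluation on the held-out part.
#' Test samples are expanded raw (not cleaned).
#'
#' @param x,y Full dataset (samples by genes; labels).
#' @param config See [baseline_config()].
#' @param train_fraction Passed to [stratified_split()].
#' @param seed Seed for both the split and the CV folds.
#' @return Object of class `"ramrsgl_run"`: list with `fit`, `test_accuracy`,
#'   `selected_genes`, `split`, `confusion` (test confusion table).
#' @export
ramrsgl_run <- function(x, y, config = baseline_config("RAMRSGL"),
                        train_fraction = 2/3, seed = 1L) {
  x <- as.matrix(x)
  enc <- encode_labels(y)
  sp <- stratified_split(enc$y, train_fraction, seed)
  if (!all(unique(enc$y[sp$test]) %in% unique(enc$y[sp$train]))) {
    stop("a test class is absent from the training set")
  }
  fit <- ramrsgl(x[sp$train, , drop = FALSE], enc$y[sp$train],
                 config = config, seed = seed)
  pr <- predict(fit, x[sp$test, , drop = FALSE])
  acc <- mean(pr$class_index == enc$y[sp$test])
  structure(list(fit = fit, test_accuracy = acc,
                 selected_genes = fit$selected_genes, split = sp,
                 confusion = table(truth = enc$y[sp$test],
                                   predicted = pr$class_index)),
            class = "ramrsgl_run")
}

#' @export
print.ramrsgl_run <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  test accuracy: %.3f (%d test samples)\n",
              x$test_accuracy, length(x$split$test)))
  invisible(x)
}

#' Repeated random-split experiments and key genes
#'
#' Repeats [ramrsgl_run()] `n_runs` times with per-run seeds derived from the
#' master seed (`seed + run index`), and aggregates accuracy and gene counts
#' (mean and sd, denominator `n_runs - 1`). Genes selected in at least
#' `key_threshold` runs are reported as key genes — the stability rule used
#' to call a gene signature reproducible across splits.
#'
#' @param x,y Full dataset.
#' @param n_runs Number of repeated experiments (default 10).
#' @param key_threshold Minimum number of selections for a key gene
#'   (default 9).
#' @param config See [baseline_config()].
#' @param train_fraction Passed to [stratified_split()].
#' @param seed Master seed.
#' @return Object of class `"ramrsgl_repeat"`: list with `accuracy`,
#'   `n_selected` (per-run vectors), `mean_accuracy`, `sd_accuracy`,
#'   `mean_n_selected`, `sd_n_selected`, `gene_counts` (named vector of
#'   selection counts), `key_genes`, `n_runs`, `key_threshold`.
#' @export
ramrsgl_repeat <- function(x, y, n_runs = 10L, key_threshold = 9L,
                           config = baseline_config("RAMRSGL"),
                           train_fraction = 2/3, seed = 1L) {
  if (n_runs < 1L) stop("'n_runs' must be at least 1")
  if (key_threshold < 1L || key_threshold > n_runs) {
    stop("'key_threshold' must be in 1..n_runs")
  }
  runs <- lapply(seq_len(n_runs), function(r) {
    ramrsgl_run(x, y, config = config, train_fraction = train_fraction,
                seed = seed + r)
  })
  acc <- vapply(runs, `[[`, 0, "test_accuracy")
  nsel <- vapply(runs, function(r) length(r$selected_genes), 0)
  all_genes <- sort(unique(unlist(lapply(runs, `[[`, "selected_genes"))))
  counts <- vapply(all_genes, function(g)
    sum(vapply(runs, function(r) g %in% r$selected_genes, TRUE)), 0)
  names(counts) <- all_genes
  structure(list(
    accuracy = acc, n_selected = nsel,
    mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc),
    mean_n_selected = mean(nsel), sd_n_selected = stats::sd(nsel),
    gene_counts = counts,
    key_genes = names(counts)[counts >= key_threshold],
    n_runs = n_runs, key_threshold = key_threshold
  ), class = "ramrsgl_repeat")
}

#' @export
print.ramrsgl_repeat <- function(x, ...) {
  cat(sprintf("Repeated experiments: %d runs\n", x$n_runs))
  cat(sprintf("  accuracy: %.3f (sd %.3f)\n", x$mean_accuracy, x$sd_accuracy))
  cat(sprintf("  selected genes: %.1f (sd %.1f)\n",
              x$mean_n_selected, x$sd_n_selected))
  cat(sprintf("  key genes (>= %d/%d runs): %s\n", x$key_threshold, x$n_runs,
              if (length(x$key_genes)) paste(x$key_genes, collapse = ", ")
              else "none"))
  invisible(x)
}
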