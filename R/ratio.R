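# Stoichiometry (co-former ratio) prediction: a binary classifier on
# latent pair representations. Known 1:1 co-crystals dominate the record,
# so the minority ("other ratio") class is rebalanced with SMOTE before
# training a gradient-boosted tree model. Balancing touches the training
# split only; the split is made before any oversampling.

#' Binary ratio label from stoichiometric counts
#'
#' Label 0 iff the pair's counts are exactly \{1, 1\}; any other
#' stoichiometry (1:2, 1:3, 2:2, ...) is label 1. Pure function of the
#' counts.
#'
#' @param pairs A `pair_set` with `count_a`/`count_b` columns.
#' @return Integer vector of 0/1 labels.
#' @export
label_ratio <- function(pairs) {
  if (anyNA(pairs$count_a) || anyNA(pairs$count_b))
    oc_stop("missing stoichiometric counts", "oc_input_error")
  as.integer(!(pairs$count_a == 1L & pairs$count_b == 1L))
}

#' SMOTE class balancing
#'
#' Synthetic minority points are convex combinations of a minority point
#' and one of its `k` nearest minority neighbours, with a coefficient
#' uniform in (0, 1). The output has equal class counts; synthetic rows
#' are flagged. Apply to the TRAINING split only.
#'
#' @param X Numeric feature matrix.
#' @param y 0/1 labels (both classes present; minority size >= 2).
#' @param k Neighbour count for the interpolation (default 5).
#' @param seed Integer seed.
#' @return A list: `X`, `y`, `synthetic` (logical flag per row).
#' @export
balance_classes <- function(X, y, k = 5L, seed = 1L) {
  X <- as.matrix(X); y <- as.integer(y)
  tab <- table(factor(y, levels = c(0L, 1L)))
  if (any(tab == 0L))
    oc_stop("both classes must be present to balance", "oc_input_error")
  if (tab[1] == tab[2])
    return(list(X = X, y = y, synthetic = rep(FALSE, nrow(X))))
  minority <- as.integer(names(tab)[which.min(tab)])
  need <- abs(diff(tab))
  mi <- which(y == minority)
  if (length(mi) < 2L)
    oc_stop("minority class needs >= 2 points for interpolation",
            "oc_input_error")
  Xm <- X[mi, , drop = FALSE]
  k_eff <- min(k, length(mi) - 1L)
  D <- cross_dist(Xm, Xm); diag(D) <- Inf
  nn <- t(matrix(apply(D, 1, function(r) order(r)[seq_len(k_eff)]),
                 nrow = k_eff))
  synth <- with_seed(seed, {
    base <- sample(length(mi), need, replace = TRUE)
    pick <- vapply(base, function(b)
      nn[b, sample(k_eff, 1L)], integer(1))
    lam <- stats::runif(need)
    Xm[base, , drop = FALSE] +
      lam * (Xm[pick, , drop = FALSE] - Xm[base, , drop = FALSE])
  })
  list(X = rbind(X, synth),
       y = c(y, rep(minority, need)),
       synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, need)))
}

# ---- Gradient-boosted trees (logistic loss, Newton leaves) -------------

gbt_leaf <- function(G, H, lambda) -G / (H + lambda)

gbt_grow <- function(X, g, h, idx, depth, max_depth, min_n, lambda) {
  G <- sum(g[idx]); H <- sum(h[idx])
  if (depth >= max_depth || length(idx) < 2L * min_n)
    return(list(leaf = TRUE, value = gbt_leaf(G, H, lambda)))
  base_obj <- G^2 / (H + lambda)
  best <- list(gain = 1e-12)
  for (j in seq_len(ncol(X))) {
    ord <- idx[order(X[idx, j])]
    xs <- X[ord, j]
    gl <- cumsum(g[ord]); hl <- cumsum(h[ord])
    n <- length(ord)
    valid <- seq_len(n - 1L)
    valid <- valid[xs[valid] < xs[valid + 1L] &
                     valid >= min_n & (n - valid) >= min_n]
    if (length(valid) == 0L) next
    gain <- gl[valid]^2 / (hl[valid] + lambda) +
      (G - gl[valid])^2 / (H - hl[valid] + lambda) - base_obj
    b <- which.max(gain)
    if (gain[b] > best$gain)
      best <- list(gain = gain[b], feature = j,
                   split = (xs[valid[b]] + xs[valid[b] + 1L]) / 2)
  }
  if (is.null(best$feature))
    return(list(leaf = TRUE, value = gbt_leaf(G, H, lambda)))
  left <- idx[X[idx, best$feature] < best$split]
  right <- idx[X[idx, best$feature] >= best$split]
  list(leaf = FALSE, feature = best$feature, split = best$split,
       left = gbt_grow(X, g, h, left, depth + 1L, max_depth, min_n, lambda),
       right = gbt_grow(X, g, h, right, depth + 1L, max_depth, min_n, lambda))
}

gbt_tree_predict <- function(node, X, idx, out) {
  if (node$leaf) { out[idx] <- node$value; return(out) }
  go <- X[idx, node$feature] < node$split
  if (any(go)) out <- gbt_tree_predict(node$left, X, idx[go], out)
  if (any(!go)) out <- gbt_tree_predict(node$right, X, idx[!go], out)
  out
}

#' Fit a gradient-boosted tree binary classifier
#'
#' Additive depth-limited regression trees fit to the gradient of the
#' logistic loss, with second-order (Newton) leaf values and shrinkage.
#' Deterministic (no row/column subsampling).
#'
#' @param X Numeric feature matrix.
#' @param y 0/1 labels.
#' @param n_trees Boosting rounds (default 100).
#' @param max_depth Tree depth (default 3).
#' @param learning_rate Shrinkage (default 0.1).
#' @param min_n Minimum rows per leaf (default 5).
#' @param lambda L2 regularization on leaf values (default 1).
#' @return An object of class `gbt_model`.
#' @export
fit_gbt <- function(X, y, n_trees = 100L, max_depth = 3L,
                    learning_rate = 0.1, min_n = 5L, lambda = 1) {
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), nrow(X) == length(y))
  p0 <- min(max(mean(y), 1e-6), 1 - 1e-6)
  f0 <- log(p0 / (1 - p0))
  f <- rep(f0, nrow(X))
  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    p <- 1 / (1 + exp(-f))
    g <- p - y
    h <- p * (1 - p)
    tree <- gbt_grow(X, g, h, seq_len(nrow(X)), 0L, max_depth, min_n, lambda)
    trees[[t]] <- tree
    f <- f + learning_rate *
      gbt_tree_predict(tree, X, seq_len(nrow(X)), numeric(nrow(X)))
  }
  structure(list(f0 = f0, trees = trees, learning_rate = learning_rate,
                 d = ncol(X)), class = "gbt_model")
}

#' Class-1 probabilities from a gradient-boosted tree model
#' @param model A `gbt_model`.
#' @param X Feature matrix with the training dimensionality.
#' @return Numeric vector of probabilities.
#' @export
predict_gbt <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$d)
    oc_stop(sprintf("expected %d features, got %d", model$d, ncol(X)),
            "oc_input_error")
  f <- rep(model$f0, nrow(X))
  for (tree in model$trees)
    f <- f + model$learning_rate *
      gbt_tree_predict(tree, X, seq_len(nrow(X)), numeric(nrow(X)))
  1 / (1 + exp(-f))
}

#' Train the stoichiometry classifier
#'
#' Splits the labelled data into train/test BEFORE balancing, SMOTE-
#' balances the training split only, then runs a small sequential search
#' over the boosting hyperparameters (rounds, depth, shrinkage) scored by
#' inner 3-fold accuracy on the balanced training set.
#'
#' @param X Numeric matrix of pair representations (typically deep
#'   latents; raw pair features are a valid ablation input).
#' @param y 0/1 ratio labels from [label_ratio()].
#' @param budget Hyperparameter evaluations (default 12).
#' @param seed Integer seed (split, SMOTE, search).
#' @param test_fraction Held-out fraction (default 0.25, stratified).
#' @return An object of class `ratio_classifier`: `model` (a
#'   `gbt_model`), `accuracy_train`, `accuracy_test`, `params`,
#'   `class_counts` (pre/post balancing), split indices.
#' @export
train_ratio_classifier <- function(X, y, budget = 12L, seed = 1L,
                                   test_fraction = 0.25) {
  X <- as.matrix(X); y <- as.integer(y)
  if (!all(is.finite(X))) oc_stop("non-finite features", "oc_input_error")
  if (length(unique(y)) < 2L)
    oc_stop("need both ratio classes to train", "oc_input_error")
  test_idx <- with_seed(derive_seed(seed, 1L), {
    idx0 <- which(y == 0L); idx1 <- which(y == 1L)
    c(sample(idx0, max(1L, round(test_fraction * length(idx0)))),
      sample(idx1, max(1L, round(test_fraction * length(idx1)))))
  })
  if (length(test_idx) >= length(y) - 1L)
    oc_stop("degenerate train/test split", "oc_input_error")
  train_idx <- setdiff(seq_along(y), test_idx)
  pre_counts <- table(factor(y[train_idx], levels = c(0L, 1L)))
  bal <- balance_classes(X[train_idx, , drop = FALSE], y[train_idx],
                         seed = derive_seed(seed, 2L))
  post_counts <- table(factor(bal$y, levels = c(0L, 1L)))
  space <- list(n_trees = list(type = "int", lo = 50, hi = 200),
                max_depth = list(type = "int", lo = 2, hi = 4),
                learning_rate = list(type = "num", lo = 0.05, hi = 0.3))
  inner_folds <- with_seed(derive_seed(seed, 3L),
                           sample(rep_len(1:3, length(bal$y))))
  eval_hp <- function(hp) {
    acc <- numeric(3)
    for (f in 1:3) {
      tr <- inner_folds != f
      m <- fit_gbt(bal$X[tr, , drop = FALSE], bal$y[tr],
                   n_trees = hp$n_trees, max_depth = hp$max_depth,
                   learning_rate = hp$learning_rate)
      acc[f] <- mean((predict_gbt(m, bal$X[!tr, , drop = FALSE]) > 0.5) ==
                       (bal$y[!tr] == 1L))
    }
    mean(acc)
  }
  best <- NULL; best_acc <- -Inf
  n_random <- max(1L, ceiling(budget / 3))
  for (i in seq_len(budget)) {
    hp <- with_seed(derive_seed(seed, 100L + i), {
      if (i > n_random && stats::runif(1) < 0.8) perturb_space(best, space)
      else sample_space(space)
    })
    a <- eval_hp(hp)
    if (a > best_acc) { best_acc <- a; best <- hp }
  }
  model <- fit_gbt(bal$X, bal$y, n_trees = best$n_trees,
                   max_depth = best$max_depth,
                   learning_rate = best$learning_rate)
  acc_train <- mean((predict_gbt(model, X[train_idx, , drop = FALSE]) > 0.5) ==
                      (y[train_idx] == 1L))
  acc_test <- mean((predict_gbt(model, X[test_idx, , drop = FALSE]) > 0.5) ==
                     (y[test_idx] == 1L))
  structure(list(model = model, accuracy_train = acc_train,
                 accuracy_test = acc_test, params = best,
                 inner_accuracy = best_acc,
                 class_counts = list(pre = pre_counts, post = post_counts),
                 train_idx = train_idx, test_idx = test_idx),
            class = "ratio_classifier")
}

#' @export
print.ratio_classifier <- function(x, ...) {
  cat(sprintf("<ratio_classifier: train acc %.3f, test acc %.3f (trees=%d, depth=%d, lr=%.2f)>\n",
              x$accuracy_train, x$accuracy_test, x$params$n_trees,
              x$params$max_depth, x$params$learning_rate))
  invisible(x)
}

#' Predict ratio classes for candidate pairs
#'
#' @param classifier A [train_ratio_classifier()] result.
#' @param X Matrix of pair representations.
#' @return A data.frame: `label` (0 = 1:1, 1 = other), `prob_11`,
#'   `prob_other` (rows sum to 1).
#' @export
predict_ratio_class <- function(classifier, X) {
  stopifnot(inherits(classifier, "ratio_classifier"))
  p1 <- predict_gbt(classifier$model, X)
  data.frame(label = as.integer(p1 > 0.5), prob_11 = 1 - p1, prob_other = p1)
}
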