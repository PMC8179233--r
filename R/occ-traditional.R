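# Public contract over the traditional one-class detectors: specs, the
# contamination-quantile threshold, score normalization, ensembling,
# cross-validated TPR and sequential hyperparameter search.

#' Detector specification
#'
#' @param family One of [detector_families()].
#' @param hyperparameters Named list of family hyperparameters (defaults
#'   applied per family at fit time).
#' @param contamination Assumed fraction of noise within the known class,
#'   in (0, 0.5); sets the inlier threshold at the contamination-quantile
#'   of training scores (default 0.05: 95% of the known data are treated
#'   as inliers).
#' @param seed Integer seed for the stochastic families.
#' @return An object of class `detector_spec`.
#' @export
detector_spec <- function(family, hyperparameters = list(),
                          contamination = 0.05, seed = 1L) {
  if (!family %in% detector_families())
    oc_stop(paste0("unknown family '", family, "'"), "oc_input_error")
  check_scalar(contamination)
  if (contamination <= 0 || contamination >= 0.5)
    oc_stop("contamination must lie in (0, 0.5)", "oc_input_error")
  structure(list(family = family, hyperparameters = hyperparameters,
                 contamination = contamination, seed = as.integer(seed)),
            class = "detector_spec")
}

#' @export
print.detector_spec <- function(x, ...) {
  hp <- if (length(x$hyperparameters))
    paste(names(x$hyperparameters), unlist(x$hyperparameters),
          sep = "=", collapse = ", ") else "defaults"
  cat(sprintf("<detector_spec: %s (%s), contamination %g, seed %d>\n",
              x$family, hp, x$contamination, x$seed))
  invisible(x)
}

#' Fit a one-class detector
#'
#' Fits the family on the training pair-vectors and fixes the inlier
#' threshold at the contamination-quantile of the training scores: with
#' `floor(c * n) + 1` as the order statistic, a fraction `1 - c` of the
#' training rows satisfies `score >= threshold` (up to quantile ties).
#'
#' @param spec A [detector_spec()].
#' @param X Numeric training matrix (rows = pair vectors), all finite.
#' @return An object of class `detector_model` with elements `spec`,
#'   `state`, `threshold`, `train_scores` and `d`.
#' @export
fit_detector <- function(spec, X) {
  stopifnot(inherits(spec, "detector_spec"))
  X <- as.matrix(X)
  if (nrow(X) == 0L) oc_stop("empty training set", "oc_input_error")
  if (!all(is.finite(X))) oc_stop("non-finite training features",
                                  "oc_input_error")
  fam <- .oc_families[[spec$family]]
  state <- fam$fit(X, spec$hyperparameters, spec$seed)
  train_scores <- fam$score(state, X)
  n <- length(train_scores)
  kth <- min(floor(spec$contamination * n) + 1L, n)
  threshold <- sort(train_scores)[kth]
  structure(list(spec = spec, state = state, threshold = threshold,
                 train_scores = train_scores, d = ncol(X)),
            class = "detector_model")
}

#' @export
print.detector_model <- function(x, ...) {
  cat(sprintf("<detector_model: %s, %d features, threshold %.4g>\n",
              x$spec$family, x$d, x$threshold))
  invisible(x)
}

#' Oriented raw scores of a fitted detector
#'
#' Higher = more inlier for every family (anomaly-high native scores are
#' multiplied by -1 inside the family implementations). Deterministic for
#' a fixed model.
#'
#' @param model A [fit_detector()] result.
#' @param X Matrix with the training dimensionality.
#' @return Numeric vector of oriented raw scores.
#' @export
score_detector <- function(model, X) {
  stopifnot(inherits(model, "detector_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$d)
    oc_stop(sprintf("expected %d features, got %d", model$d, ncol(X)),
            "oc_input_error")
  .oc_families[[model$spec$family]]$score(model$state, X)
}

#' Inlier flags at the fitted contamination threshold
#' @param model A `detector_model`.
#' @param X Matrix to score (raw scores are compared to the threshold).
#' @return Logical vector (`TRUE` = inlier).
#' @export
is_inlier <- function(model, X) {
  score_detector(model, X) >= model$threshold
}

#' Min-max normalize scores over a reference set
#'
#' Maps the reference minimum to 0 and maximum to 1 (order-preserving
#' affine map); scores outside the reference range map outside \[0, 1\].
#' In the screening workflow the reference set is the union of labelled
#' and candidate scores for the same model, so every reported score lands
#' in \[0, 1\].
#'
#' @param raw Numeric scores to normalize.
#' @param reference Numeric scores defining the range (default `raw`).
#' @return Normalized scores.
#' @export
normalize_scores <- function(raw, reference = raw) {
  lo <- min(reference); hi <- max(reference)
  if (hi == lo) {
    warning("constant reference scores: mapping everything to 0.5")
    return(rep(0.5, length(raw)))
  }
  (raw - lo) / (hi - lo)
}

#' Ensemble score: mean of the per-model normalized scores
#'
#' @param score_matrix Numeric matrix, one column per model, rows = pairs,
#'   all columns normalized to \[0, 1\]; `NA` entries (missing model
#'   columns) are an error.
#' @return Numeric vector of per-pair ensemble scores.
#' @export
ensemble_average <- function(score_matrix) {
  score_matrix <- as.matrix(score_matrix)
  if (anyNA(score_matrix))
    oc_stop("missing model scores in ensemble input", "oc_input_error")
  rowMeans(score_matrix)
}

#' Symmetrized per-pair score
#'
#' Averages the raw scores of the rows sharing a `pair_id` (i.e. the two
#' orientations of each pair), guaranteeing exact invariance of the
#' reported score under molecule order.
#'
#' @param model A `detector_model`.
#' @param X Pair-vector matrix carrying a `pair_id` attribute (as built by
#'   [build_pair_vectors()]).
#' @return Named numeric vector of one score per unique pair, in first-
#'   occurrence order.
#' @export
symmetrized_pair_score <- function(model, X) {
  pid <- attr(X, "pair_id")
  if (is.null(pid)) oc_stop("X must carry a pair_id attribute",
                            "oc_input_error")
  raw <- score_detector(model, X)
  ids <- unique(pid)
  out <- vapply(split(raw, factor(pid, levels = ids)), mean, numeric(1))
  out[ids]
}

#' Assemble the full score table
#'
#' Scores labelled and candidate pair-vectors with every fitted model,
#' symmetrizes over orientations, min-max normalizes each model's scores
#' over the union of both datasets, flags inliers against each model's
#' raw threshold, and appends the ensemble column (arithmetic mean of the
#' per-model normalized scores).
#'
#' @param models Named list of `detector_model`s.
#' @param X_labelled,X_candidate Pair-vector matrices with `pair_id`
#'   attributes.
#' @return A data.frame of class `score_table`: `pair_id`, `dataset`, one
#'   normalized score column per model, `ensemble`, and one
#'   `inlier_<model>` logical column per model.
#' @export
build_score_table <- function(models, X_labelled, X_candidate) {
  stopifnot(length(models) > 0, !is.null(names(models)))
  ids_l <- unique(attr(X_labelled, "pair_id"))
  ids_c <- unique(attr(X_candidate, "pair_id"))
  out <- data.frame(pair_id = c(ids_l, ids_c),
                    dataset = rep(c("labelled", "candidate"),
                                  c(length(ids_l), length(ids_c))),
                    stringsAsFactors = FALSE)
  norm_cols <- matrix(NA_real_, nrow(out), length(models),
                      dimnames = list(NULL, names(models)))
  for (m in names(models)) {
    raw_l <- symmetrized_pair_score(models[[m]], X_labelled)
    raw_c <- symmetrized_pair_score(models[[m]], X_candidate)
    raw <- c(raw_l, raw_c)
    norm_cols[, m] <- normalize_scores(raw, raw)
    out[[paste0("inlier_", m)]] <- raw >= models[[m]]$threshold
  }
  for (m in names(models)) out[[m]] <- norm_cols[, m]
  out$ensemble <- ensemble_average(norm_cols)
  class(out) <- c("score_table", "data.frame")
  out
}

#' Fold assignment that never splits a pair's orientations
#'
#' @param pair_id Character vector (one entry per row, repeated across
#'   orientations).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold label per row.
#' @export
pair_folds <- function(pair_id, k, seed = 1L) {
  ids <- unique(pair_id)
  if (k < 2L || k > length(ids))
    oc_stop("k must lie in [2, number of distinct pairs]", "oc_input_error")
  fold_of <- with_seed(seed,
                       stats::setNames(sample(rep_len(seq_len(k),
                                                      length(ids))), ids))
  unname(fold_of[pair_id])
}

#' Cross-validated true-positive rate
#'
#' Five-fold (by default) cross validation on the labelled pairs: fit on
#' 4/5 of the pairs (both orientations of a pair always land in the same
#' fold), then count the validation rows scoring at or above the training
#' threshold. TPR = accepted validation rows / validation size.
#'
#' @param spec A [detector_spec()].
#' @param X Labelled pair-vector matrix with a `pair_id` attribute.
#' @param k Number of folds (default 5).
#' @param seed Seed for the fold assignment.
#' @return A list with `per_fold`, `mean` and `sd`.
#' @export
crossval_tpr <- function(spec, X, k = 5L, seed = 1L) {
  pid <- attr(X, "pair_id")
  if (is.null(pid)) oc_stop("X must carry a pair_id attribute",
                            "oc_input_error")
  folds <- pair_folds(pid, k, seed)
  tpr <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    Xtr <- X[tr, , drop = FALSE]
    attr(Xtr, "pair_id") <- pid[tr]
    model <- fit_detector(spec, Xtr)
    tpr[f] <- mean(is_inlier(model, X[!tr, , drop = FALSE]))
  }
  list(per_fold = tpr, mean = mean(tpr), sd = stats::sd(tpr))
}

#' Default hyperparameter search spaces
#'
#' Standard ranges per family (neighbour counts, tree counts, kernel
#' width, cluster counts, mixture components, bin counts); every range is
#' overridable through the `space` argument of [tune_detector()].
#'
#' @param family One of [detector_families()].
#' @return Named list of parameter descriptors
#'   (`list(type = "int"|"num"|"lognum", lo, hi)`).
#' @export
default_search_space <- function(family) {
  switch(family,
    gaussian_mixture_density = list(
      n_components = list(type = "int", lo = 1, hi = 6)),
    local_outlier_factor = list(
      n_neighbors = list(type = "int", lo = 5, hi = 50)),
    knn_distance = list(
      k = list(type = "int", lo = 1, hi = 30)),
    isolation_forest = list(
      n_trees = list(type = "int", lo = 50, hi = 200)),
    one_class_svm = list(
      gamma = list(type = "lognum", lo = 1e-3, hi = 10),
      nu = list(type = "num", lo = 0.01, hi = 0.3)),
    histogram_density = list(
      n_bins = list(type = "int", lo = 5, hi = 30)),
    cluster_based_lof = list(
      n_clusters = list(type = "int", lo = 2, hi = 12)),
    feature_bagged_lof = list(
      n_neighbors = list(type = "int", lo = 5, hi = 50),
      n_bags = list(type = "int", lo = 5, hi = 15)),
    oc_stop(paste("no search space for", family), "oc_input_error"))
}

sample_space <- function(space) {
  out <- list()
  for (p in names(space)) {
    s <- space[[p]]
    out[[p]] <- switch(s$type,
      int = sample(seq(s$lo, s$hi), 1L),
      num = stats::runif(1, s$lo, s$hi),
      lognum = exp(stats::runif(1, log(s$lo), log(s$hi))))
  }
  out
}

perturb_space <- function(hp, space) {
  out <- hp
  for (p in names(space)) {
    s <- space[[p]]
    if (s$type == "int") {
      width <- max(1, round(0.15 * (s$hi - s$lo)))
      out[[p]] <- min(max(hp[[p]] + sample(seq(-width, width), 1L), s$lo),
                      s$hi)
    } else if (s$type == "num") {
      out[[p]] <- min(max(hp[[p]] + stats::rnorm(1, 0, 0.15 * (s$hi - s$lo)),
                          s$lo), s$hi)
    } else {
      lg <- log(hp[[p]]) + stats::rnorm(1, 0, 0.15 * (log(s$hi) - log(s$lo)))
      out[[p]] <- exp(min(max(lg, log(s$lo)), log(s$hi)))
    }
  }
  out
}

#' Sequential hyperparameter search maximizing cross-validated TPR
#'
#' Sequential model-based search in the Hyperopt spirit: an initial
#' random exploration phase, after which most proposals are perturbations
#' of the incumbent best configuration, so later proposals concentrate
#' near earlier high scorers. Reproducible given the seed.
#'
#' @param spec Template [detector_spec()] (family, contamination, seed).
#' @param X Labelled pair-vector matrix with a `pair_id` attribute.
#' @param budget Number of evaluations (>= 1).
#' @param seed Search seed.
#' @param k Cross-validation folds.
#' @param space Search space (default [default_search_space()]).
#' @return A list with `best_spec`, `best_tpr` and a `history` data.frame
#'   (one row per evaluation: parameters, mean TPR, proposal kind).
#' @export
tune_detector <- function(spec, X, budget = 25L, seed = 1L, k = 5L,
                          space = default_search_space(spec$family)) {
  if (length(space) == 0L) oc_stop("empty search space", "oc_input_error")
  if (budget < 1L) oc_stop("budget must be >= 1", "oc_input_error")
  n_random <- max(1L, min(budget, ceiling(budget / 3)))
  history <- vector("list", budget)
  best <- NULL; best_tpr <- -Inf
  for (i in seq_len(budget)) {
    kind <- if (i <= n_random) "random" else
      with_seed(derive_seed(seed, 1000L + i),
                if (stats::runif(1) < 0.8) "local" else "random")
    hp <- with_seed(derive_seed(seed, i), {
      if (kind == "local") perturb_space(best$hyperparameters, space)
      else sample_space(space)
    })
    cand <- detector_spec(spec$family, hp, spec$contamination, spec$seed)
    tpr <- crossval_tpr(cand, X, k = k, seed = derive_seed(seed, 5000L + i))$mean
    history[[i]] <- data.frame(eval = i, kind = kind, tpr = tpr,
                               t(unlist(hp)))
    if (tpr > best_tpr) { best_tpr <- tpr; best <- cand }
  }
  list(best_spec = best, best_tpr = best_tpr,
       history = do.call(rbind, history))
}
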