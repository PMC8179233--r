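# Shapley-value attribution of (deep) scores and mapping of opaque
# important descriptors to interpretable ones via correlation.
#
# Attributions are interventional: the value of a coalition S is the
# mean model output after splicing the explained pair's S-features into
# the background sample. Exact enumeration over all 2^p coalitions is
# used up to `exact_limit` features; above that a seeded permutation
# estimator with a reported Monte-Carlo error takes over. Attribution is
# computed on the raw (pre-normalization) score: attributing an affine
# transform of the score merely rescales the values.

#' Shapley attribution of a score function over pair vectors
#'
#' @param score_fun Deterministic function: numeric matrix -> numeric
#'   vector (e.g. `function(X) -deep_distance(model, X)`).
#' @param background Numeric matrix of background pair vectors (the
#'   reference distribution; typically a seeded subsample of the labelled
#'   pairs, default size 100 upstream).
#' @param X Numeric matrix of pairs to explain.
#' @param exact_limit Maximum feature count for exact enumeration
#'   (default 12).
#' @param n_perm Permutations for the sampling estimator.
#' @param seed Seed for the sampling estimator.
#' @return An object of class `attribution_table`: `values` (pairs x
#'   features), `baseline` (mean background score), `scores` (score of
#'   each explained pair), `global` (mean |value| per feature),
#'   `method`, and `mc_se` (permutation estimator only).
#' @export
shapley_attribution <- function(score_fun, background, X,
                                exact_limit = 12L, n_perm = 256L,
                                seed = 1L) {
  background <- as.matrix(background); X <- as.matrix(X)
  if (nrow(background) == 0L) oc_stop("empty background", "oc_input_error")
  if (ncol(background) != ncol(X))
    oc_stop("background and X feature counts differ", "oc_input_error")
  s1 <- score_fun(background); s2 <- score_fun(background)
  if (!isTRUE(all.equal(s1, s2, tolerance = 0)))
    oc_stop("score_fun is not deterministic; attribution requires a pure function",
            "oc_input_error")
  p <- ncol(X)
  baseline <- mean(s1)
  scores <- score_fun(X)
  if (p <= exact_limit) {
    values <- t(vapply(seq_len(nrow(X)), function(i)
      shapley_exact_row(score_fun, background, X[i, ]), numeric(p)))
    method <- "exact"; mc_se <- NULL
  } else {
    res <- lapply(seq_len(nrow(X)), function(i)
      shapley_perm_row(score_fun, background, X[i, ], n_perm,
                       derive_seed(seed, i)))
    values <- t(vapply(res, `[[`, numeric(p), "phi"))
    mc_se <- t(vapply(res, `[[`, numeric(p), "se"))
    method <- "permutation"
  }
  colnames(values) <- colnames(X)
  structure(list(values = values, baseline = baseline, scores = scores,
                 global = colMeans(abs(values)), method = method,
                 mc_se = mc_se),
            class = "attribution_table")
}

# exact interventional Shapley values for one explained row
shapley_exact_row <- function(score_fun, background, x) {
  p <- length(x)
  nb <- nrow(background)
  nsub <- bitwShiftL(1L, p)
  v <- numeric(nsub)
  for (s in seq_len(nsub) - 1L) {
    M <- background
    for (j in seq_len(p))
      if (bitwAnd(s, bitwShiftL(1L, j - 1L)) != 0L) M[, j] <- x[j]
    v[s + 1L] <- mean(score_fun(M))
  }
  lf <- lfactorial(0:p)
  phi <- numeric(p)
  for (s in seq_len(nsub) - 1L) {
    size <- sum(bitwAnd(s, bitwShiftL(1L, 0:(p - 1L))) != 0L)
    w <- exp(lf[size + 1L] + lf[p - size] - lf[p + 1L])
    for (j in seq_len(p)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(s, bit) == 0L)
        phi[j] <- phi[j] + w * (v[bitwOr(s, bit) + 1L] - v[s + 1L])
    }
  }
  phi
}

# permutation-sampling estimator with per-feature Monte-Carlo error
shapley_perm_row <- function(score_fun, background, x, n_perm, seed) {
  p <- length(x)
  contrib <- matrix(0, n_perm, p)
  perms <- with_seed(seed, replicate(n_perm, sample(p), simplify = FALSE))
  for (m in seq_len(n_perm)) {
    M <- background
    prev <- mean(score_fun(M))
    for (j in perms[[m]]) {
      M[, j] <- x[j]
      cur <- mean(score_fun(M))
      contrib[m, j] <- cur - prev
      prev <- cur
    }
  }
  list(phi = colMeans(contrib),
       se = apply(contrib, 2, stats::sd) / sqrt(n_perm))
}

#' @export
print.attribution_table <- function(x, ...) {
  cat(sprintf("<attribution_table: %d pairs x %d features (%s estimator)>\n",
              nrow(x$values), ncol(x$values), x$method))
  invisible(x)
}

#' Map important opaque descriptors to interpretable ones
#'
#' For each of the top-ranked important descriptors (by global |Shapley|
#' importance), lists the interpretable descriptors whose absolute
#' Pearson correlation across molecules exceeds `r_min`.
#'
#' @param global_importance Named numeric vector of per-feature
#'   importances (e.g. `attribution$global`), named by descriptor.
#' @param descriptors Numeric matrix (molecules x descriptors) with
#'   column names covering both opaque and interpretable descriptors.
#' @param interpretable Character vector of interpretable descriptor
#'   column names (e.g. polarity, volume, branching analogues).
#' @param r_min Absolute-correlation threshold (default 0.75).
#' @param n_top How many top important descriptors to map (default 6).
#' @return An object of class `descriptor_correlation_map`: a named list
#'   of data.frames (`interpretable`, `r`) sorted by |r| descending.
#' @export
map_to_interpretable <- function(global_importance, descriptors,
                                 interpretable, r_min = 0.75, n_top = 6L) {
  if (length(interpretable) == 0L)
    oc_stop("empty interpretable descriptor set", "oc_input_error")
  descriptors <- as.matrix(descriptors)
  if (is.null(colnames(descriptors)))
    oc_stop("descriptor matrix needs column names", "oc_input_error")
  missing <- setdiff(interpretable, colnames(descriptors))
  if (length(missing) > 0L)
    oc_stop(paste("interpretable descriptors absent from the matrix:",
                  paste(missing, collapse = ", ")), "oc_reference_error")
  top <- names(sort(global_importance, decreasing = TRUE))
  top <- utils::head(top[top %in% colnames(descriptors)], n_top)
  out <- lapply(top, function(f) {
    r <- vapply(interpretable, function(g)
      stats::cor(descriptors[, f], descriptors[, g]), numeric(1))
    r[is.na(r)] <- 0
    hit <- abs(r) > r_min
    df <- data.frame(interpretable = interpretable[hit], r = r[hit],
                     stringsAsFactors = FALSE)
    df[order(-abs(df$r)), , drop = FALSE]
  })
  names(out) <- top
  structure(out, class = "descriptor_correlation_map", r_min = r_min)
}

#' Global importances restricted to a subset of pairs
#'
#' @param attribution An `attribution_table`.
#' @param subset Logical or integer index selecting >= 1 explained pair.
#' @return Named numeric vector: mean |Shapley| per feature over the
#'   subset.
#' @export
subset_attribution <- function(attribution, subset) {
  stopifnot(inherits(attribution, "attribution_table"))
  vals <- attribution$values[subset, , drop = FALSE]
  if (nrow(vals) == 0L) oc_stop("empty pair subset", "oc_input_error")
  colMeans(abs(vals))
}
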