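# Descriptor engineering: pruning, molecular-complementarity selection,
# [0,1] scaling fitted on the labelled molecules, and pair-vector
# construction (optionally bidirectional for order-invariant training).

#' Prune redundant and uninformative descriptors
#'
#' Removes descriptors with variance below `var_min`, then walks the
#' remaining columns in order and drops any column whose absolute Pearson
#' correlation with an already-kept column exceeds `corr_max` (the later
#' column of a correlated pair loses; deterministic).
#'
#' @param X Numeric matrix, molecules x descriptors, no missing values.
#' @param corr_max Pairwise absolute-correlation ceiling (default 0.92).
#' @param var_min Variance floor (default 0.4).
#' @return Integer vector of surviving column indices (possibly empty,
#'   with a warning when nothing survives).
#' @export
prune_descriptors <- function(X, corr_max = 0.92, var_min = 0.4) {
  X <- as.matrix(X)
  if (ncol(X) < 1L) oc_stop("descriptor matrix has no columns", "oc_input_error")
  if (anyNA(X))
    oc_stop("descriptor matrix contains missing values; drop incomplete molecules first",
            "oc_input_error")
  v <- apply(X, 2, stats::var)
  cand <- unname(which(v >= var_min))
  if (length(cand) == 0L) {
    warning("no descriptor survives the variance filter")
    return(integer(0))
  }
  cm <- abs(stats::cor(X[, cand, drop = FALSE]))
  cm[is.na(cm)] <- 0
  kept <- integer(0)
  for (j in seq_along(cand)) {
    if (length(kept) == 0L || all(cm[j, kept] <= corr_max))
      kept <- c(kept, j)
  }
  cand[kept]
}

#' Flag benzene-like solvent molecules
#'
#' The complementarity analysis is run after removing co-crystals that
#' contain benzene-like solvents, which would otherwise bias the feature
#' importances. "Benzene-like" here means: a single ring with at most one
#' substituent attachment, or membership of the configured solvent list.
#'
#' @param molecules A `molecule_set`.
#' @param cfg A [filter_config()] (solvent list).
#' @param backend A `chem_backend` (ring statistics).
#' @return Logical vector over the molecules.
#' @export
benzene_like_solvents <- function(molecules, cfg = filter_config(),
                                  backend = default_chem_backend()) {
  stopifnot(inherits(molecules, "molecule_set"))
  smi <- molecules$table$smiles
  if (length(smi) == 0L) return(logical(0))
  info <- ring_info(backend, smi)
  single_ring <- info$n_rings == 1L & info$n_substituents <= 1L
  listed <- canonicalize_smiles(backend, smi) %in%
    canonicalize_smiles(backend, cfg$nonaromatic_solvent_smiles)
  single_ring | listed
}

#' Select complementarity features across co-former pairs
#'
#' For each descriptor, correlates co-former A's value with co-former B's
#' value across the labelled pairs. Both orientations contribute
#' symmetrically: the estimate is computed on the stacked bidirectional
#' table, so it is exactly invariant under a global A/B swap. A descriptor
#' is kept iff Pearson r > `corr_min` AND Spearman rho > `corr_min` AND
#' both two-sided p-values < `p_max`; p-values use the number of distinct
#' pairs as the sample size (not the doubled stacked table).
#'
#' @param desc_a,desc_b Numeric matrices (pairs x descriptors): descriptor
#'   values of co-former A and co-former B of each labelled pair, after
#'   pruning and after removing solvent-containing pairs.
#' @param corr_min Correlation floor for both methods (default 0.4).
#' @param p_max P-value ceiling for both methods (default 1e-3).
#' @return A list of class `feature_selection`: `kept` (column indices),
#'   `pearson_r`, `spearman_r`, `pearson_p`, `spearman_p`, thresholds and
#'   `n_pairs`.
#' @export
select_complementary_features <- function(desc_a, desc_b, corr_min = 0.4,
                                          p_max = 1e-3) {
  desc_a <- as.matrix(desc_a); desc_b <- as.matrix(desc_b)
  if (!identical(dim(desc_a), dim(desc_b)))
    oc_stop("desc_a and desc_b must have identical dimensions",
            "oc_input_error")
  n <- nrow(desc_a)
  if (n < 3L)
    oc_stop("need at least 3 labelled pairs for correlation p-values; supply a larger dataset",
            "oc_input_error")
  a2 <- rbind(desc_a, desc_b)  # stacked bidirectional table
  b2 <- rbind(desc_b, desc_a)
  p_of <- function(r) {
    r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  d <- ncol(desc_a)
  pearson <- numeric(d); spearman <- numeric(d)
  for (j in seq_len(d)) {
    pearson[j] <- stats::cor(a2[, j], b2[, j])
    spearman[j] <- stats::cor(a2[, j], b2[, j], method = "spearman")
  }
  pearson[is.na(pearson)] <- 0; spearman[is.na(spearman)] <- 0
  pp <- p_of(pearson); sp <- p_of(spearman)
  kept <- which(pearson > corr_min & spearman > corr_min &
                  pp < p_max & sp < p_max)
  structure(list(kept = kept, pearson_r = pearson, spearman_r = spearman,
                 pearson_p = pp, spearman_p = sp,
                 corr_min = corr_min, p_max = p_max, n_pairs = n),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf("<feature_selection: %d of %d descriptors kept (r > %g, p < %g, n = %d pairs)>\n",
              length(x$kept), length(x$pearson_r), x$corr_min, x$p_max,
              x$n_pairs))
  invisible(x)
}

#' Fit a min-max scaler on the labelled molecules
#'
#' Per-feature linear map of the fitting set onto \[0, 1\]. The scaler is
#' fitted once on the molecules known to form co-crystals and then applied
#' to every molecule (labelled or candidate) so the same molecule always
#' receives the same representation; candidate values may fall outside
#' \[0, 1\] and are not clipped.
#'
#' @param X Numeric matrix (fitting molecules x features).
#' @return An object of class `minmax_scaler`.
#' @export
fit_minmax_scaler <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) oc_stop("empty fitting set", "oc_input_error")
  mn <- apply(X, 2, min); mx <- apply(X, 2, max)
  if (any(mx == mn))
    warning(sprintf("%d zero-range feature(s) will map to 0",
                    sum(mx == mn)))
  structure(list(min = mn, max = mx), class = "minmax_scaler")
}

#' Apply a fitted min-max scaler
#'
#' @param scaler A [fit_minmax_scaler()] result.
#' @param X Numeric matrix with the fitted feature count.
#' @return The scaled matrix (unclipped).
#' @export
scale_features <- function(scaler, X) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  X <- as.matrix(X)
  if (ncol(X) != length(scaler$min))
    oc_stop("feature count differs from the fitted scaler", "oc_input_error")
  rng <- scaler$max - scaler$min
  out <- sweep(X, 2, scaler$min, "-")
  nz <- rng > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, rng[nz], "/")
  out[, !nz] <- 0
  out
}

#' Invert a min-max scaling (non-degenerate features only)
#' @param scaler A `minmax_scaler`.
#' @param X Scaled matrix.
#' @return Matrix on the original scale.
#' @export
unscale_features <- function(scaler, X) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  X <- as.matrix(X)
  sweep(sweep(X, 2, scaler$max - scaler$min, "*"), 2, scaler$min, "+")
}

#' Build pair feature vectors by concatenation
#'
#' Each pair becomes the concatenation of its two molecules' scaled
#' feature vectors. With `bidirectional = TRUE` (training) both
#' orientations are emitted so position-dependent models see each pair in
#' both orders; with `FALSE` one canonical orientation (sorted mol_id) is
#' emitted per pair.
#'
#' @param pairs A `pair_set`.
#' @param features Numeric matrix of per-molecule (scaled) features with
#'   rownames = mol_id.
#' @param bidirectional Emit both orientations per pair?
#' @return Numeric matrix with `2 * ncol(features)` columns and attributes
#'   `pair_id` and `orientation` (`"ab"`/`"ba"`), one row per emitted
#'   orientation.
#' @export
build_pair_vectors <- function(pairs, features, bidirectional = TRUE) {
  stopifnot(inherits(pairs, "pair_set"))
  features <- as.matrix(features)
  if (is.null(rownames(features)))
    oc_stop("features must carry mol_id rownames", "oc_input_error")
  need <- unique(c(pairs$mol_a, pairs$mol_b))
  missing <- setdiff(need, rownames(features))
  if (length(missing) > 0L)
    oc_stop(paste("no features for molecules:",
                  paste(missing, collapse = ", ")), "oc_reference_error")
  fa <- features[pairs$mol_a, , drop = FALSE]
  fb <- features[pairs$mol_b, , drop = FALSE]
  ab <- cbind(fa, fb)
  if (bidirectional) {
    X <- rbind(ab, cbind(fb, fa))
    pid <- c(pairs$pair_id, pairs$pair_id)
    orient <- rep(c("ab", "ba"), each = nrow(pairs))
  } else {
    X <- ab
    pid <- pairs$pair_id
    orient <- rep("ab", nrow(pairs))
  }
  dimnames(X) <- NULL
  attr(X, "pair_id") <- pid
  attr(X, "orientation") <- orient
  X
}

#' Swap the two halves of pair vectors
#'
#' Utility producing the opposite orientation of already-built pair rows.
#' @param X Pair-vector matrix with an even column count.
#' @return Matrix with the two halves exchanged.
#' @export
swap_pair_halves <- function(X) {
  X <- as.matrix(X)
  k <- ncol(X) / 2
  if (k != floor(k)) oc_stop("pair vectors must have even length",
                             "oc_input_error")
  X[, c((k + 1):(2 * k), 1:k), drop = FALSE]
}
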