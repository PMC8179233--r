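# Candidate selection: thresholding, top-quartile extraction, co-former
# popularity, Pareto-front prioritisation, nearest known pairs and the
# 2D-projection distance-preservation QC.

#' Selection configuration
#'
#' @param threshold Inlier score threshold in \[0, 1\] (default 0.7:
#'   pairs scoring strictly above are regarded as reliable inliers).
#' @param quartile_fraction Top fraction for popularity counting
#'   (default 0.25).
#' @param reference_smiles Reference molecule for the similarity
#'   objective of the Pareto search (default TCNQ).
#' @param exclude_one_ring,exclude_heteroatoms Novelty constraint flags.
#' @param fixed_coformer Optional mol_id restricting pairs to one
#'   co-former (e.g. pyrene).
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(threshold = 0.7, quartile_fraction = 0.25,
                             reference_smiles = "N#CC(C#N)=C1C=CC(C=C1)=C(C#N)C#N",
                             exclude_one_ring = FALSE,
                             exclude_heteroatoms = FALSE,
                             fixed_coformer = NULL) {
  check_scalar(threshold, 0, 1)
  check_scalar(quartile_fraction, 0, 1)
  structure(list(threshold = threshold,
                 quartile_fraction = quartile_fraction,
                 reference_smiles = reference_smiles,
                 exclude_one_ring = exclude_one_ring,
                 exclude_heteroatoms = exclude_heteroatoms,
                 fixed_coformer = fixed_coformer),
            class = "selection_config")
}

#' Flag reliable inliers by score threshold
#'
#' Returns the pairs whose score is strictly greater than the threshold.
#'
#' @param scores Named numeric vector (names = pair ids) or a
#'   `score_table` column extracted by the caller.
#' @param threshold Score threshold (default 0.7).
#' @return The scores of the retained pairs (named subset, same order).
#' @export
flag_inliers <- function(scores, threshold = 0.7) {
  scores[scores > threshold]
}

#' Top-fraction extraction by score
#'
#' Returns the `floor(n * fraction)` highest-scoring pairs; ties broken
#' deterministically by pair id (lexicographic).
#'
#' @param scores Named numeric vector (names = pair ids).
#' @param fraction Fraction to keep (default 0.25).
#' @return Named numeric vector of the retained scores, sorted by
#'   descending score.
#' @export
top_quartile <- function(scores, fraction = 0.25) {
  n <- length(scores)
  if (n == 0L) return(scores)
  keep <- floor(n * fraction)
  ord <- order(-scores, names(scores))
  scores[ord[seq_len(keep)]]
}

#' Co-former popularity in a pair subset
#'
#' Each pair contributes one appearance to each of its two molecules; the
#' result is ranked by descending count with deterministic (mol_id) ties.
#'
#' @param pairs A `pair_set` (or data.frame with `mol_a`, `mol_b`).
#' @return A data.frame `mol_id`, `count`, ranked.
#' @export
coformer_popularity <- function(pairs) {
  if (nrow(pairs) == 0L)
    return(data.frame(mol_id = character(0), count = integer(0)))
  cnt <- table(c(pairs$mol_a, pairs$mol_b))
  df <- data.frame(mol_id = names(cnt), count = as.integer(cnt),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$mol_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Pareto front under two maximization objectives
#'
#' A candidate x dominates y iff x >= y in both objectives and x > y in
#' at least one; the front is the non-dominated set (exact duplicates are
#' kept on the front together).
#'
#' @param objectives Numeric matrix or data.frame with two columns (e.g.
#'   model score and reference Tanimoto similarity), finite values.
#' @return Logical vector `on_front`, one element per candidate.
#' @export
pareto_front <- function(objectives) {
  objectives <- as.matrix(objectives)
  if (ncol(objectives) != 2L)
    oc_stop("exactly two objectives expected", "oc_input_error")
  if (!all(is.finite(objectives)))
    oc_stop("objectives must be finite", "oc_input_error")
  n <- nrow(objectives)
  if (n == 0L) return(logical(0))
  o1 <- objectives[, 1]; o2 <- objectives[, 2]
  ord <- order(-o1, -o2)
  on_front <- logical(n)
  best_higher <- -Inf       # max o2 among strictly higher o1
  i <- 1L
  while (i <= n) {
    # group of equal o1
    j <- i
    while (j < n && o1[ord[j + 1L]] == o1[ord[i]]) j <- j + 1L
    grp <- ord[i:j]
    grp_max <- max(o2[grp])
    # front members of this o1-group: maximal o2 within the group and not
    # matched/beaten by any strictly-higher-o1 point
    on_front[grp] <- (o2[grp] == grp_max) & (grp_max > best_higher)
    best_higher <- max(best_higher, grp_max)
    i <- j + 1L
  }
  on_front
}

#' k nearest known pairs by Euclidean distance
#'
#' Distance between the query pair and each labelled pair is symmetrized:
#' the minimum over the two orientations of the labelled pair vector.
#' Ties are broken by pair id; `k` larger than the dataset returns the
#' full sorted list with a warning.
#'
#' @param query Numeric vector (one pair, length `2k`).
#' @param labelled Pair-vector matrix (one canonical orientation per
#'   pair) with a `pair_id` attribute.
#' @param k Number of neighbours.
#' @return A data.frame `pair_id`, `distance`, ascending.
#' @export
nearest_known_pairs <- function(query, labelled, k = 8L) {
  pid <- attr(labelled, "pair_id")
  if (is.null(pid)) oc_stop("labelled matrix must carry pair_id",
                            "oc_input_error")
  q <- matrix(as.numeric(query), 1L)
  if (ncol(q) != ncol(labelled))
    oc_stop("query and labelled dimensionality differ", "oc_input_error")
  d1 <- as.numeric(cross_dist(q, labelled))
  d2 <- as.numeric(cross_dist(q, swap_pair_halves(labelled)))
  d <- pmin(d1, d2)
  agg <- tapply(d, pid, min)
  df <- data.frame(pair_id = names(agg), distance = as.numeric(agg),
                   stringsAsFactors = FALSE)
  df <- df[order(df$distance, df$pair_id), , drop = FALSE]
  if (k > nrow(df)) {
    warning(sprintf("k = %d exceeds the %d labelled pairs; returning all",
                    k, nrow(df)))
    k <- nrow(df)
  }
  rownames(df) <- NULL
  df[seq_len(k), , drop = FALSE]
}

#' 2D projection with distance-preservation QC
#'
#' Projects the pair vectors to 2D and reports the Pearson correlation
#' between the condensed pairwise-distance matrices in full dimension and
#' in 2D — the quantity that measures how faithfully the projection
#' preserves the geometry. The projection algorithm is an exchangeable
#' external component: `"pca"` (deterministic, default) or `"umap"`
#' (delegated to the python umap-learn backend, honouring
#' `n_neighbours`/`min_dist`); precomputed coordinates can also be passed
#' for QC only.
#'
#' @param X Numeric matrix of pair vectors.
#' @param n_neighbours Neighbourhood size (umap backend; also the
#'   minimum-points check: `nrow(X)` must exceed it).
#' @param min_dist Minimum embedding distance (umap backend).
#' @param seed Integer seed (umap backend).
#' @param method `"pca"` or `"umap"`.
#' @param coords Optional precomputed 2-column coordinate matrix.
#' @return A list: `coords` (n x 2), `qc` (Pearson r of the two condensed
#'   distance vectors), `method`.
#' @export
embed_2d_qc <- function(X, n_neighbours = 80L, min_dist = 0.1, seed = 1L,
                        method = c("pca", "umap"), coords = NULL) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (is.null(coords) && nrow(X) < n_neighbours + 1L)
    oc_stop(sprintf("need at least %d points for n_neighbours = %d",
                    n_neighbours + 1L, n_neighbours), "oc_input_error")
  if (is.null(coords)) {
    if (method == "pca") {
      pc <- stats::prcomp(X, rank. = 2L)
      coords <- pc$x[, 1:2, drop = FALSE]
    } else {
      res <- chem_call(rdkit_chem_backend(), "umap_embed",
                       list(matrix = apply(X, 1, as.numeric,
                                           simplify = FALSE),
                            n_neighbours = n_neighbours,
                            min_dist = min_dist, seed = seed))
      coords <- do.call(rbind, lapply(res$coords, unlist))
    }
  } else {
    coords <- as.matrix(coords)
    method <- "precomputed"
  }
  qc <- stats::cor(as.numeric(stats::dist(X)),
                   as.numeric(stats::dist(coords)))
  list(coords = coords, qc = qc, method = method)
}

#' Apply novelty constraints to candidate pairs
#'
#' Implements the constrained high-score searches: optionally remove
#' pairs containing single-ring molecules, pairs containing heteroatom
#' molecules, or restrict to pairs containing one fixed co-former; and
#' flag pairs whose non-fixed member is already a known co-former.
#'
#' @param pairs A `pair_set` of candidates.
#' @param molecules A `molecule_set` covering the pairs' members.
#' @param cfg A [selection_config()].
#' @param known_coformers Character vector of mol_ids already seen in
#'   known co-crystals (for the `has_known_cocrystals` flag).
#' @param backend A `chem_backend` (ring statistics; only consulted when
#'   a structural constraint is enabled).
#' @return The filtered `pair_set` with an added logical column
#'   `has_known_cocrystals`.
#' @export
apply_novelty_constraints <- function(pairs, molecules,
                                      cfg = selection_config(),
                                      known_coformers = character(0),
                                      backend = default_chem_backend()) {
  stopifnot(inherits(pairs, "pair_set"), inherits(molecules, "molecule_set"))
  keep <- rep(TRUE, nrow(pairs))
  if (isTRUE(cfg$exclude_one_ring) || isTRUE(cfg$exclude_heteroatoms)) {
    info <- ring_info(backend, molecules$table$smiles)
    bad <- rep(FALSE, nrow(molecules$table))
    if (isTRUE(cfg$exclude_one_ring)) bad <- bad | info$n_rings <= 1L
    if (isTRUE(cfg$exclude_heteroatoms)) bad <- bad | info$has_heteroatom
    bad_ids <- molecules$table$mol_id[bad]
    keep <- keep & !(pairs$mol_a %in% bad_ids | pairs$mol_b %in% bad_ids)
  }
  if (!is.null(cfg$fixed_coformer))
    keep <- keep & (pairs$mol_a == cfg$fixed_coformer |
                      pairs$mol_b == cfg$fixed_coformer)
  out <- pairs[keep, , drop = FALSE]
  if (is.null(cfg$fixed_coformer)) {
    out$has_known_cocrystals <- out$mol_a %in% known_coformers |
      out$mol_b %in% known_coformers
  } else {
    # novelty of the non-fixed member is what matters in a fixed-co-former
    # search (the fixed co-former is known by construction)
    partner <- ifelse(out$mol_a == cfg$fixed_coformer, out$mol_b, out$mol_a)
    out$has_known_cocrystals <- partner %in% known_coformers
  }
  class(out) <- c("pair_set", "data.frame")
  out
}
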