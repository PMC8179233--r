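# Seeded synthetic-fixture generators.
#
# The generators emulate the statistical structure the screening
# workflow assumes, so every module is testable without any database or
# proprietary descriptor software: descriptor matrices with correlated
# blocks and constant columns (exercising the pruning filters), a set of
# "key" descriptors driven by a one-dimensional latent molecular
# property, labelled pairs whose co-formers are matched on that latent
# (producing the cross-co-former complementarity correlation), planted
# outlier pairs drawn without that matching, a dominant 1:1 stoichiometry
# class, and candidate pairs with a known planted-inlier fraction.
# Everything is a pure function of the seed.

#' Fixture specification
#'
#' Defaults state the world the test-suite assumes: 500 labelled pairs
#' (the scale at which complementarity selection is expected to recover
#' the planted feature set), a cross-co-former correlation of 0.85 for
#' the key descriptors (comfortably above the 0.4 selection floor, below
#' the 0.92 redundancy ceiling), 5% planted outliers (matching the workflow's assumed known-class noise), and an 80% share
#' of 1:1 stoichiometry.
#'
#' @param n_molecules Molecule pool size.
#' @param n_descriptors Total descriptor count.
#' @param n_complementary Planted key descriptors (pairwise correlated
#'   across co-formers).
#' @param n_correlated_block Near-duplicate descriptors (r ~ 0.99)
#'   exercising the redundancy pruning.
#' @param n_constant Constant descriptors exercising the variance filter.
#' @param n_labelled_pairs Labelled pair count.
#' @param outlier_fraction Planted-outlier share of the labelled pairs.
#' @param correlation Target cross-co-former Pearson correlation of the
#'   key descriptors, in (0, 0.95].
#' @param ratio_11_share Share of 1:1 stoichiometry labels.
#' @param ratio_rule `"random"` (Bernoulli labels) or `"planted"`
#'   (deterministic function of the pair's latent values, marginally
#'   respecting `ratio_11_share`).
#' @param seed Integer master seed.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_molecules = 150L, n_descriptors = 60L,
                         n_complementary = 8L, n_correlated_block = 4L,
                         n_constant = 2L, n_labelled_pairs = 500L,
                         outlier_fraction = 0.05, correlation = 0.85,
                         ratio_11_share = 0.8,
                         ratio_rule = c("random", "planted"), seed = 1L) {
  ratio_rule <- match.arg(ratio_rule)
  check_scalar(n_molecules, 2); check_scalar(n_descriptors, 1)
  check_scalar(outlier_fraction, 0, 1); check_scalar(ratio_11_share, 0, 1)
  check_scalar(correlation, 0, 0.95)
  if (n_complementary + n_correlated_block + n_constant > n_descriptors)
    oc_stop("planted column groups exceed n_descriptors", "oc_input_error")
  structure(list(n_molecules = as.integer(n_molecules),
                 n_descriptors = as.integer(n_descriptors),
                 n_complementary = as.integer(n_complementary),
                 n_correlated_block = as.integer(n_correlated_block),
                 n_constant = as.integer(n_constant),
                 n_labelled_pairs = as.integer(n_labelled_pairs),
                 outlier_fraction = outlier_fraction,
                 correlation = correlation,
                 ratio_11_share = ratio_11_share,
                 ratio_rule = ratio_rule,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# small pool of valid placeholder SMILES (fused aromatics); fixture
# molecules are NOT chemically modelled, ids carry the identity
.fixture_smiles_pool <- c(
  "c1ccccc1", "c1ccc2ccccc2c1", "c1ccc2cc3ccccc3cc2c1",
  "c1cc2ccc3cccc4ccc(c1)c2c34", "c1ccc2c(c1)ccc1ccccc12",
  "c1ccc-2c(c1)-c1cccc3cccc-2c13")

#' Generate the fixture molecule pool
#'
#' Descriptor layout (column order): `n_complementary` key descriptors
#' (affine in the molecule's latent property + noise, variance > 0.4),
#' `n_correlated_block` near-duplicates of one noise column (pairwise
#' r ~ 0.99), `n_constant` constant columns, remaining columns
#' independent noise.
#'
#' @param spec A [fixture_spec()].
#' @return A list: `molecules` (a `molecule_set` with descriptors),
#'   `latent` (per-molecule property), `core` (indices of on-manifold
#'   molecules), `key_features`, `correlated_block`, `constant_cols`,
#'   `family_features` (index vectors), `spec`.
#' @export
generate_molecules <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_molecules; d <- spec$n_descriptors
  nk <- spec$n_complementary; nb <- spec$n_correlated_block
  nc <- spec$n_constant
  with_seed(derive_seed(spec$seed, 1L), {
    # Core molecules lie on the known-class property manifold: one
    # latent property drives every loaded descriptor. A fringe quarter
    # has a scrambled profile — each loaded descriptor draws its own
    # independent, broadened latent — emulating candidate catalogues
    # that contain molecules off the known-class manifold. Fringe
    # molecules only ever appear in non-matched (outlier) pairs.
    n_fringe <- round(0.25 * n)
    core <- seq_len(n - n_fringe)
    fringe <- setdiff(seq_len(n), core)
    t <- c(stats::rnorm(n - n_fringe), stats::rnorm(n_fringe, 0, 1.5))
    latent_col <- function() {
      tj <- t
      tj[fringe] <- stats::rnorm(length(fringe), 0, 1.5)
      tj
    }
    D <- matrix(0, n, d)
    sigma_f <- sqrt(0.15)  # key-descriptor noise; attenuation 1/1.15
    for (j in seq_len(nk)) {
      scale_j <- stats::runif(1, 1, 3)
      D[, j] <- scale_j * (stats::runif(1, -2, 2) + latent_col() +
                             sigma_f * stats::rnorm(n))
    }
    if (nb > 0L) {
      base <- stats::rnorm(n)
      for (j in seq_len(nb))
        D[, nk + j] <- stats::runif(1, 1, 2) *
          (base + 0.05 * stats::rnorm(n))
    }
    if (nc > 0L)
      for (j in seq_len(nc)) D[, nk + nb + j] <- stats::runif(1, -1, 1)
    # remaining columns: half are "property family" descriptors — weakly
    # loaded on the same latent property (cross-pair correlation ~ 0.1,
    # safely below the 0.4 complementarity threshold) emulating the heavy
    # redundancy of real descriptor sets; the rest are independent noise
    rest <- seq((nk + nb + nc + 1L), length.out = d - nk - nb - nc)
    nf <- length(rest) %/% 2
    family <- rest[seq_len(nf)]
    sigma_fam <- 3   # attenuation ~ 0.1: family dims stay well below the 0.4 selection floor
    for (j in family)
      D[, j] <- stats::runif(1, 1, 2) *
        (sample(c(-1, 1), 1) * latent_col() + sigma_fam * stats::rnorm(n))
    for (j in setdiff(rest, family))
      D[, j] <- stats::runif(1, 1, 2) * stats::rnorm(n)
    colnames(D) <- sprintf("D%03d", seq_len(d))
    mols <- molecule_set(
      mol_id = sprintf("M%03d", seq_len(n)),
      smiles = rep_len(.fixture_smiles_pool, n),
      descriptors = D, source = "labelled")
    list(molecules = mols, latent = t, core = core,
         key_features = seq_len(nk),
         correlated_block = nk + seq_len(nb),
         constant_cols = nk + nb + seq_len(nc),
         family_features = family,
         spec = spec)
  })
}

# pick, for each target latent value, the pool molecule with the nearest
# latent (excluding a given partner index)
match_latent <- function(latent, target, exclude) {
  vapply(seq_along(target), function(i) {
    d <- abs(latent - target[i])
    d[exclude[i]] <- Inf
    which.min(d)
  }, integer(1))
}

# draw unique unordered pairs: inliers latent-matched (with nearest-
# neighbour rank jitter to escape duplicate collisions), outliers
# independent; called inside a with_seed block
draw_unique_pairs <- function(latent, core, n_pairs, outlier_fraction, r_t) {
  n <- length(latent)
  fringe_d <- rep(0, n); fringe_d[setdiff(seq_len(n), core)] <- Inf
  seen <- character(0)
  a_out <- integer(0); b_out <- integer(0); out_flag <- logical(0)
  tries <- 0L
  while (length(a_out) < n_pairs && tries < 60L) {
    tries <- tries + 1L
    m <- max(n_pairs - length(a_out), 16L)
    is_outlier <- stats::runif(m) < outlier_fraction
    a <- sample(core, m, replace = TRUE)
    a[is_outlier] <- sample(n, sum(is_outlier), replace = TRUE)
    target <- r_t * latent[a] + sqrt(1 - r_t^2) * stats::rnorm(m)
    # inlier partners: latent-matched within the core; after the first
    # sweep, pick among the nearest few so repeated (a, target)
    # collisions can still produce new pairs
    b <- vapply(seq_len(m), function(i) {
      d <- abs(latent - target[i]) + fringe_d
      d[a[i]] <- Inf
      if (tries == 1L) which.min(d)
      else order(d)[sample.int(min(tries, 8L), 1L)]
    }, integer(1))
    b[is_outlier] <- vapply(which(is_outlier), function(i) {
      cand <- sample(n, 1L)
      while (cand == a[i]) cand <- sample(n, 1L)
      cand
    }, integer(1))
    key <- pair_id_of(as.character(a), as.character(b))
    fresh <- !(key %in% seen) & !duplicated(key)
    seen <- c(seen, key[fresh])
    a_out <- c(a_out, a[fresh]); b_out <- c(b_out, b[fresh])
    out_flag <- c(out_flag, is_outlier[fresh])
  }
  if (length(a_out) < n_pairs)
    oc_stop("could not draw enough unique pairs; enlarge the molecule pool",
            "oc_input_error")
  keep <- seq_len(n_pairs)
  list(a = a_out[keep], b = b_out[keep], is_outlier = out_flag[keep])
}

#' Generate labelled pairs with planted structure
#'
#' Inlier pairs match co-formers on the latent property (yielding the
#' configured cross-co-former correlation on the key descriptors, via a
#' latent correlation corrected for the key-descriptor noise
#' attenuation); planted outlier pairs combine independently drawn
#' molecules. Stoichiometry labels follow `ratio_11_share` (Bernoulli,
#' or the planted deterministic rule).
#'
#' @param spec A [fixture_spec()].
#' @param mols A [generate_molecules()] result for the same spec.
#' @return A list: `pairs` (a `pair_set`, label `known_cocrystal`),
#'   `is_outlier` (ground truth), `ratio_label` (0/1 ground truth).
#' @export
generate_labelled_pairs <- function(spec, mols) {
  n_pairs <- spec$n_labelled_pairs
  latent <- mols$latent
  n <- length(latent)
  if (n < 3L) oc_stop("need at least 3 molecules", "oc_input_error")
  attenuation <- 1 / 1.15   # matches sigma_f^2 = 0.15 in generate_molecules
  r_t <- min(spec$correlation / attenuation, 0.995)
  if (n_pairs > n * (n - 1) / 2)
    oc_stop("more labelled pairs requested than distinct pairs exist",
            "oc_input_error")
  with_seed(derive_seed(spec$seed, 2L), {
    drawn <- draw_unique_pairs(latent, mols$core, n_pairs, spec$outlier_fraction, r_t)
    a <- drawn$a; b <- drawn$b; is_outlier <- drawn$is_outlier
    ratio_label <- if (spec$ratio_rule == "random") {
      as.integer(stats::runif(n_pairs) >= spec$ratio_11_share)
    } else {
      s <- latent[a] + latent[b]
      as.integer(s > stats::quantile(s, spec$ratio_11_share))
    }
    ids <- mols$molecules$table$mol_id
    pairs <- pair_set(ids[a], ids[b], label = "known_cocrystal",
                      count_a = 1L,
                      count_b = ifelse(ratio_label == 1L, 2L, 1L))
    list(pairs = pairs, is_outlier = is_outlier, ratio_label = ratio_label)
  })
}

#' Generate candidate pairs with a planted inlier fraction
#'
#' @param spec A [fixture_spec()].
#' @param mols A [generate_molecules()] result.
#' @param n_pairs Number of candidate pairs.
#' @param inlier_fraction Fraction generated with the inlier (latent-
#'   matched) mechanism; the rest are independent combinations.
#' @return A list: `pairs` (label `candidate`), `is_planted_inlier`.
#' @export
generate_candidate_pairs <- function(spec, mols, n_pairs = 200L,
                                     inlier_fraction = 0.3) {
  latent <- mols$latent
  n <- length(latent)
  attenuation <- 1 / 1.15
  r_t <- min(spec$correlation / attenuation, 0.995)
  with_seed(derive_seed(spec$seed, 3L), {
    drawn <- draw_unique_pairs(latent, mols$core, n_pairs, 1 - inlier_fraction, r_t)
    ids <- mols$molecules$table$mol_id
    list(pairs = pair_set(ids[drawn$a], ids[drawn$b], label = "candidate"),
         is_planted_inlier = !drawn$is_outlier)
  })
}

#' Generate the full fixture bundle
#'
#' @param spec A [fixture_spec()].
#' @param n_candidates Candidate pair count.
#' @param candidate_inlier_fraction Planted inlier share among candidates.
#' @return A list: `molecules` (the [generate_molecules()] result),
#'   `labelled` (the [generate_labelled_pairs()] result), `candidates`
#'   (the [generate_candidate_pairs()] result), `spec`.
#' @export
generate_fixture <- function(spec, n_candidates = 200L,
                             candidate_inlier_fraction = 0.3) {
  mols <- generate_molecules(spec)
  list(molecules = mols,
       labelled = generate_labelled_pairs(spec, mols),
       candidates = generate_candidate_pairs(spec, mols, n_candidates,
                                             candidate_inlier_fraction),
       spec = spec)
}

#' Area under the ROC curve (rank statistic)
#'
#' Tie-aware Mann-Whitney AUC used by the recovery experiments: the
#' probability that a random positive outscores a random negative.
#'
#' @param score Numeric scores (higher = predicted positive).
#' @param truth Logical: `TRUE` for the positive class.
#' @return AUC in \[0, 1\].
#' @export
rank_auc <- function(score, truth) {
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L)
    oc_stop("need both classes for AUC", "oc_input_error")
  r <- rank(score)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
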