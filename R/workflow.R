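# End-to-end screening workflow: featurization, the traditional
# detector ensemble, and the deep hypersphere branch, mirroring the
# two-step design (train on the known class, then score known +
# candidate pairs together).

#' Run the co-crystal screening workflow
#'
#' Featurizes (prune, complementarity selection, min-max scaling fitted
#' on the labelled molecules), trains the eight traditional one-class
#' detectors on bidirectional pair vectors over the selected features,
#' optionally trains the deep hypersphere model on the full
#' dimensionality, and assembles the normalized score table over the
#' union of labelled and candidate pairs.
#'
#' @param descriptors Numeric matrix (molecules x descriptors) with
#'   mol_id rownames, no missing values.
#' @param labelled_pairs A `pair_set` of known co-crystal pairs.
#' @param candidate_pairs A `pair_set` of candidate pairs.
#' @param contamination Assumed known-class noise (default 0.05).
#' @param seed Master seed.
#' @param families Detector families to fit (default all eight).
#' @param hyperparameters Optional named list (family -> named list).
#' @param deep Fit the deep branch too? (default TRUE)
#' @param deep_config Optional [encoder_config()] override.
#' @param corr_max,var_min,pair_corr_min,p_max Featurization thresholds.
#' @return A list of class `screening_result`: `selected_features`,
#'   `selection`, `scaler`, `models`, `deep_model`, `scores` (a
#'   `score_table` with an added `deep` column when `deep = TRUE`).
#' @export
run_screening <- function(descriptors, labelled_pairs, candidate_pairs,
                          contamination = 0.05, seed = 1L,
                          families = detector_families(),
                          hyperparameters = list(),
                          deep = TRUE, deep_config = NULL,
                          corr_max = 0.92, var_min = 0.4,
                          pair_corr_min = 0.4, p_max = 1e-3) {
  descriptors <- as.matrix(descriptors)
  if (is.null(rownames(descriptors)))
    oc_stop("descriptors must carry mol_id rownames", "oc_input_error")
  lab_mols <- unique(c(labelled_pairs$mol_a, labelled_pairs$mol_b))
  D_lab <- descriptors[lab_mols, , drop = FALSE]
  kept <- prune_descriptors(D_lab, corr_max = corr_max, var_min = var_min)
  sel <- select_complementary_features(
    descriptors[labelled_pairs$mol_a, kept, drop = FALSE],
    descriptors[labelled_pairs$mol_b, kept, drop = FALSE],
    corr_min = pair_corr_min, p_max = p_max)
  feats <- kept[sel$kept]
  if (length(feats) == 0L)
    oc_stop("no complementarity feature survived selection", "oc_fit_error")
  scaler <- suppressWarnings(fit_minmax_scaler(D_lab))
  S <- scale_features(scaler, descriptors)
  rownames(S) <- rownames(descriptors)
  Sf <- S[, feats, drop = FALSE]
  Xl <- build_pair_vectors(labelled_pairs, Sf, bidirectional = TRUE)
  Xc <- build_pair_vectors(candidate_pairs, Sf, bidirectional = TRUE)
  models <- lapply(families, function(f)
    fit_detector(detector_spec(f, hyperparameters[[f]] %||% list(),
                               contamination = contamination,
                               seed = derive_seed(seed, match(f, families))),
                 Xl))
  names(models) <- families
  scores <- build_score_table(models, Xl, Xc)
  deep_model <- NULL
  if (deep) {
    XlF <- build_pair_vectors(labelled_pairs, S, bidirectional = FALSE)
    XcF <- build_pair_vectors(candidate_pairs, S, bidirectional = FALSE)
    cfg <- deep_config %||% encoder_config(d = ncol(S), seed = seed)
    enc <- pretrain_autoencoder(cfg, XlF)
    deep_model <- train_one_class(enc, compute_center(enc, XlF), XlF)
    ref <- rbind(XlF, XcF)
    sd_all <- score_deep(deep_model, ref, reference = ref)
    scores$deep <- sd_all[match(scores$pair_id,
                                c(attr(XlF, "pair_id"), attr(XcF, "pair_id")))]
  }
  structure(list(selected_features = feats, selection = sel, scaler = scaler,
                 models = models, deep_model = deep_model, scores = scores),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("<screening_result: %d selected features, %d detectors%s, %d scored pairs>\n",
              length(x$selected_features), length(x$models),
              if (!is.null(x$deep_model)) " + deep hypersphere" else "",
              nrow(x$scores)))
  invisible(x)
}

#' Recovery benchmark on one synthetic fixture
#'
#' Runs the full screening workflow on a generated fixture and measures
#' the recovery quantities used by the acceptance suite: whether the
#' planted complementarity features are recovered exactly, and how well
#' the ensemble and the deep branch separate planted candidate inliers
#' from non-matched candidate pairs (rank AUC).
#'
#' @param seed Fixture and model seed.
#' @param spec Optional [fixture_spec()] override (its seed is replaced).
#' @param n_candidates Candidate pairs to score.
#' @param deep Include the deep branch?
#' @param deep_config Optional [encoder_config()] override.
#' @return A list: `exact_recovery`, `ensemble_auc`, `deep_auc` (NA when
#'   `deep = FALSE`), `n_selected`.
#' @export
fixture_benchmark <- function(seed, spec = NULL, n_candidates = 300L,
                              deep = TRUE, deep_config = NULL) {
  if (is.null(spec)) spec <- fixture_spec(seed = seed)
  else spec$seed <- as.integer(seed)
  fx <- generate_fixture(spec, n_candidates = n_candidates)
  D <- fx$molecules$molecules$descriptors
  res <- run_screening(D, fx$labelled$pairs, fx$candidates$pairs,
                       seed = seed, deep = deep,
                       deep_config = deep_config)
  exact <- identical(res$selected_features, fx$molecules$key_features)
  cand <- res$scores[res$scores$dataset == "candidate", ]
  stopifnot(identical(cand$pair_id, fx$candidates$pairs$pair_id))
  truth <- fx$candidates$is_planted_inlier
  list(exact_recovery = exact,
       ensemble_auc = rank_auc(cand$ensemble, truth),
       deep_auc = if (deep) rank_auc(cand$deep, truth) else NA_real_,
       n_selected = length(res$selected_features))
}
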