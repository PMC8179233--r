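# Traditional one-class detectors: contamination contract, oracles,
# normalization, ensembling, symmetrization, cross-validation, tuning.

test_that("every family honours the contamination-quantile contract (n = 400)", {
  set.seed(31)
  X <- matrix(rnorm(400 * 6), 400, 6)
  for (fam in detector_families()) {
    m <- fit_detector(detector_spec(fam, contamination = 0.05, seed = 3L), X)
    n_in <- sum(is_inlier(m, X))
    expect_true(abs(n_in - 380) <= 1,
                label = sprintf("%s: %d of 400 inliers", fam, n_in))
  }
})

test_that("scoring is deterministic and dimension-checked for every family", {
  set.seed(32)
  X <- matrix(rnorm(80 * 4), 80, 4)
  Q <- matrix(rnorm(10 * 4), 10, 4)
  for (fam in detector_families()) {
    m <- fit_detector(detector_spec(fam, seed = 9L), X)
    expect_identical(score_detector(m, Q), score_detector(m, Q),
                     label = fam)
    expect_error(score_detector(m, Q[, 1:3]), class = "oc_input_error")
  }
})

test_that("a point at the blob mean outscores a point 10 sigma away, all families", {
  set.seed(33)
  X <- matrix(rnorm(150 * 3, sd = 1), 150, 3)
  Q <- rbind(colMeans(X), colMeans(X) + 10)
  for (fam in detector_families()) {
    s <- score_detector(fit_detector(detector_spec(fam, seed = 2L), X), Q)
    expect_gt(s[1], s[2], label = fam)
  }
})

test_that("kNN raw score equals the exhaustive-search oracle", {
  set.seed(34)
  X <- matrix(rnorm(20 * 3), 20, 3)
  Q <- matrix(rnorm(7 * 3), 7, 3)
  for (k in c(1L, 3L, 5L)) {
    m <- fit_detector(detector_spec("knn_distance", list(k = k)), X)
    want <- apply(Q, 1, function(q)
      -sort(sqrt(colSums((t(X) - q)^2)))[k])
    expect_equal(score_detector(m, Q), want, tolerance = 1e-10)
  }
  # all-identical training rows: zero distances, everything an inlier
  Xc <- matrix(1, 30, 2)
  mc <- fit_detector(detector_spec("knn_distance"), Xc)
  expect_true(all(is_inlier(mc, Xc)))
})

test_that("planted far outliers get the lowest oriented scores for every family", {
  set.seed(35)
  # a 2-D Gaussian blob plus 5 isolated points ~12-17 sigma out
  far <- rbind(c(12, 12), c(-12, 12), c(12, -12), c(-12, -12), c(0, 17))
  X <- rbind(matrix(rnorm(200 * 2), 200, 2), far)
  truth_out <- c(rep(FALSE, 200), rep(TRUE, 5))
  # a unimodal blob warrants a single mixture component (the family's
  # appropriate spec for this world); all other families run on defaults
  hp <- list(gaussian_mixture_density = list(n_components = 1))
  for (fam in detector_families()) {
    m <- fit_detector(detector_spec(fam, hp[[fam]] %||% list(),
                                    contamination = 0.05, seed = 4L), X)
    s <- score_detector(m, X)
    expect_true(all(rank(s)[truth_out] <= 10),
                label = sprintf("%s ranks planted outliers last", fam))
  }
})

test_that("normalize_scores: affine map, rank preservation, reference semantics", {
  expect_equal(normalize_scores(c(-3, 0, 1)), c(0, 0.75, 1))
  set.seed(36)
  raw <- rnorm(50)
  ns <- normalize_scores(raw)
  expect_equal(cor(raw, ns, method = "spearman"), 1)
  expect_true(all(ns >= 0 & ns <= 1))
  # different reference -> different values, identical ranking
  ref2 <- c(raw, -10, 10)
  ns2 <- normalize_scores(raw, ref2)
  expect_false(isTRUE(all.equal(ns, ns2)))
  expect_identical(order(ns), order(ns2))
  expect_warning(out <- normalize_scores(c(1, 1, 1)))
  expect_equal(out, rep(0.5, 3))
})

test_that("ensemble average is the arithmetic mean with bounds preserved", {
  expect_equal(ensemble_average(cbind(0.2, 0.8)), 0.5)
  expect_equal(ensemble_average(cbind(1, 1, 1)), 1)
  set.seed(37)
  M <- matrix(runif(40 * 8), 40, 8)
  expect_equal(ensemble_average(M), rowMeans(M))
  expect_true(all(ensemble_average(M) >= 0 & ensemble_average(M) <= 1))
  M[3, 5] <- NA
  expect_error(ensemble_average(M), class = "oc_input_error")
})

test_that("symmetrized scores are exactly order-invariant", {
  ft <- small_featurized()
  m <- fit_detector(detector_spec("knn_distance"), ft$Xl)
  s_ab <- symmetrized_pair_score(m, ft$Xc)
  # swap the two halves of every candidate row and rescore
  Xswap <- swap_pair_halves(ft$Xc)
  attr(Xswap, "pair_id") <- attr(ft$Xc, "pair_id")
  s_ba <- symmetrized_pair_score(m, Xswap)
  expect_identical(s_ab, s_ba)
  # a symmetric model is unchanged; toy direct average
  expect_equal(unname(mean(c(0.6, 0.8))), 0.7)
})

test_that("score table: bounds, ensemble column, orientation-invariant flags", {
  ft <- small_featurized()
  fams <- c("knn_distance", "histogram_density")
  models <- lapply(fams, function(f)
    fit_detector(detector_spec(f, seed = 5L), ft$Xl))
  names(models) <- fams
  st <- build_score_table(models, ft$Xl, ft$Xc)
  expect_s3_class(st, "score_table")
  for (f in fams) {
    expect_true(all(st[[f]] >= 0 & st[[f]] <= 1))
    expect_type(st[[paste0("inlier_", f)]], "logical")
  }
  expect_equal(st$ensemble, rowMeans(as.matrix(st[, fams])))
  expect_identical(nrow(st),
                   length(unique(attr(ft$Xl, "pair_id"))) +
                     length(unique(attr(ft$Xc, "pair_id"))))
})

test_that("cross-validated TPR: fold integrity and the quantile property", {
  ft <- small_featurized()
  pid <- attr(ft$Xl, "pair_id")
  folds <- pair_folds(pid, 5L, seed = 8L)
  # both orientations of a pair always share a fold
  expect_true(all(tapply(folds, pid, function(f) length(unique(f))) == 1L))
  expect_error(pair_folds(pid, 1L), class = "oc_input_error")
  expect_error(pair_folds(pid, length(unique(pid)) + 1L),
               class = "oc_input_error")
  # on (mostly) inlier data mean TPR is close to 1 - contamination
  cv <- crossval_tpr(detector_spec("knn_distance", contamination = 0.05),
                     ft$Xl, k = 5L, seed = 8L)
  expect_length(cv$per_fold, 5L)
  expect_gt(cv$mean, 0.85)
  expect_lte(cv$mean, 1)
})

test_that("sequential tuner: budget-1 identity, determinism, concentration", {
  ft <- small_featurized()
  spec <- detector_spec("knn_distance", seed = 2L)
  # budget 1 returns the single evaluated configuration
  t1 <- tune_detector(spec, ft$Xl, budget = 1L, seed = 3L, k = 3L)
  expect_identical(nrow(t1$history), 1L)
  expect_identical(t1$best_spec$hyperparameters$k, as.integer(t1$history$k))
  # reproducible given the seed
  t2 <- tune_detector(spec, ft$Xl, budget = 6L, seed = 3L, k = 3L)
  t3 <- tune_detector(spec, ft$Xl, budget = 6L, seed = 3L, k = 3L)
  expect_identical(t2$history, t3$history)
  expect_identical(t2$best_tpr, max(t2$history$tpr))
  # later proposals concentrate near earlier high scorers
  expect_true(any(t2$history$kind == "local"))
  expect_error(tune_detector(spec, ft$Xl, budget = 0L),
               class = "oc_input_error")
  expect_error(tune_detector(spec, ft$Xl, budget = 2L, space = list()),
               class = "oc_input_error")
})

test_that("degenerate single-unique-row input errors for the density family", {
  X <- matrix(1, 20, 3)
  expect_error(fit_detector(detector_spec("gaussian_mixture_density"), X),
               class = "oc_fit_error")
  expect_error(fit_detector(detector_spec("knn_distance"),
                            matrix(numeric(0), 0, 2)),
               class = "oc_input_error")
})
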