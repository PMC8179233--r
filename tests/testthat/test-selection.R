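# Candidate selection: thresholding, quartiles, popularity, Pareto,
# nearest known pairs, 2D QC.

test_that("inlier flagging is strict and idempotent", {
  s <- c(a = 0.2, b = 0.7, c = 0.9, d = 1.0)
  expect_identical(names(flag_inliers(s, 0.7)), c("c", "d"))
  expect_identical(flag_inliers(s, 0), s)           # threshold 0 keeps all
  expect_length(flag_inliers(s, 1), 0L)             # strict: nothing > 1
  expect_identical(flag_inliers(flag_inliers(s, 0.7), 0.7),
                   flag_inliers(s, 0.7))
  # binomial expectation: uniform scores, threshold 0.7, n = 10 000
  set.seed(61)
  u <- setNames(runif(10000), sprintf("p%05d", 1:10000))
  expect_lt(abs(length(flag_inliers(u, 0.7)) - 3000), 150)
})

test_that("top-quartile equals sort-then-slice, nested, deterministic ties", {
  set.seed(62)
  s <- setNames(runif(1000), sprintf("p%04d", 1:1000))
  got <- top_quartile(s, 0.25)
  want <- sort(s, decreasing = TRUE)[1:250]
  expect_setequal(names(got), names(want))
  expect_identical(length(top_quartile(setNames(runif(4), letters[1:4]))), 1L)
  # nesting: top of top is a subset
  expect_true(all(names(top_quartile(got, 0.25)) %in% names(got)))
  # ties broken by pair id (lexicographic)
  tie <- c(b = 1, a = 1, c = 0)
  expect_identical(names(top_quartile(tie, 0.5)), "a")
})

test_that("co-former popularity: counts, ranking, handshake identity", {
  pr <- pair_set(c("A", "A", "B"), c("B", "C", "C"))
  pop <- coformer_popularity(pr)
  expect_identical(pop$count, c(2L, 2L, 2L))
  # toy from the contract: {(A,B),(A,C)} -> A:2, B:1, C:1
  pop2 <- coformer_popularity(pair_set(c("A", "A"), c("B", "C")))
  expect_identical(pop2$mol_id, c("A", "B", "C"))
  expect_identical(pop2$count, c(2L, 1L, 1L))
  expect_identical(sum(pop2$count), 2L * 2L)        # handshake
  expect_identical(nrow(coformer_popularity(pr[0, ])), 0L)
})

test_that("Pareto front equals the O(n^2) dominance oracle; trivial cases", {
  oracle <- function(M) {
    vapply(seq_len(nrow(M)), function(i) {
      !any(vapply(seq_len(nrow(M)), function(j) {
        all(M[j, ] >= M[i, ]) && any(M[j, ] > M[i, ])
      }, logical(1)))
    }, logical(1))
  }
  expect_identical(pareto_front(rbind(c(1, 0), c(0, 1), c(0.5, 0.5))),
                   rep(TRUE, 3))
  expect_identical(pareto_front(rbind(c(1, 1), c(0.5, 0.5))),
                   c(TRUE, FALSE))
  set.seed(63)
  for (rep in 1:3) {
    M <- matrix(runif(200 * 2), 200, 2)
    expect_identical(pareto_front(M), oracle(M))
  }
  # duplicated optimum: both stay on the front
  M2 <- rbind(c(1, 1), c(1, 1), c(0, 0))
  expect_identical(pareto_front(M2), c(TRUE, TRUE, FALSE))
  # ties in one objective
  M3 <- rbind(c(1, 0.5), c(1, 0.7), c(0.2, 0.9))
  expect_identical(pareto_front(M3), c(FALSE, TRUE, TRUE))
  # invariance under strictly monotone transforms of either objective
  M <- matrix(runif(100 * 2), 100, 2)
  expect_identical(pareto_front(M), pareto_front(cbind(exp(M[, 1]), M[, 2]^3)))
  expect_error(pareto_front(matrix(1, 2, 3)), class = "oc_input_error")
  expect_error(pareto_front(rbind(c(1, NA))), class = "oc_input_error")
})

test_that("nearest known pairs: oracle agreement, symmetrization, k overflow", {
  set.seed(64)
  k2 <- 4L
  L <- matrix(rnorm(50 * 2 * k2), 50, 2 * k2)
  attr(L, "pair_id") <- sprintf("p%02d", 1:50)
  q <- rnorm(2 * k2)
  got <- nearest_known_pairs(q, L, k = 50L)
  want <- pmin(sqrt(colSums((t(L) - q)^2)),
               sqrt(colSums((t(swap_pair_halves(L)) - q)^2)))
  expect_equal(got$distance, sort(want), tolerance = 1e-10)
  # query equal to a labelled pair (in swapped orientation) -> distance 0
  q2 <- swap_pair_halves(L[7, , drop = FALSE])[1, ]
  expect_identical(nearest_known_pairs(q2, L, k = 1L)$pair_id, "p07")
  expect_equal(nearest_known_pairs(q2, L, k = 1L)$distance, 0)
  expect_warning(all_out <- nearest_known_pairs(q, L, k = 60L))
  expect_identical(nrow(all_out), 50L)
})

test_that("2D QC: isometry scores 1, shuffling scores ~0, oracle on 20 points", {
  set.seed(65)
  X2 <- matrix(rnorm(40), 20, 2)
  # identity projection of already-2D data is an isometry
  qc1 <- embed_2d_qc(X2, coords = X2)
  expect_equal(qc1$qc, 1, tolerance = 1e-12)
  # shuffled coordinates destroy the distance structure
  qc0 <- embed_2d_qc(X2, coords = X2[sample(20), ])
  expect_lt(abs(qc0$qc), 0.45)
  # QC equals a hand-rolled Pearson over the 190 condensed distances
  X <- matrix(rnorm(20 * 6), 20, 6)
  co <- matrix(rnorm(40), 20, 2)
  qc <- embed_2d_qc(X, coords = co)
  d1 <- as.numeric(dist(X)); d2 <- as.numeric(dist(co))
  expect_equal(qc$qc,
               sum((d1 - mean(d1)) * (d2 - mean(d2))) /
                 sqrt(sum((d1 - mean(d1))^2) * sum((d2 - mean(d2))^2)),
               tolerance = 1e-12)
  # built-in projection path respects the minimum-points check
  expect_error(embed_2d_qc(X, n_neighbours = 80L), class = "oc_input_error")
  pca <- embed_2d_qc(X, n_neighbours = 10L, method = "pca")
  expect_identical(dim(pca$coords), c(20L, 2L))
  expect_gt(pca$qc, 0.3)   # PCA preserves a fair share of the geometry
})

test_that("selection config validates and carries the novelty flags", {
  cfg <- selection_config(threshold = 0.7)
  expect_identical(cfg$quartile_fraction, 0.25)
  expect_error(selection_config(threshold = 1.5), class = "oc_input_error")
})

test_that("novelty constraints filter pairs and flag known co-formers", {
  be <- chem()
  ms <- molecule_set(
    c("pyrene", "benzene", "dca", "anthr"),
    c("c1cc2ccc3cccc4ccc(c1)c2c34", "c1ccccc1",
      "N#Cc1ccccc1C#N", "c1ccc2cc3ccccc3cc2c1"))
  pr <- pair_set(c("pyrene", "pyrene", "benzene"),
                 c("benzene", "dca", "anthr"))
  # exclude one-ring molecules: drops every pair containing benzene or dca
  out <- apply_novelty_constraints(
    pr, ms, selection_config(exclude_one_ring = TRUE),
    known_coformers = "anthr", backend = be)
  expect_identical(nrow(out), 0L)
  # heteroatom exclusion drops the dicyanobenzene pair only
  out2 <- apply_novelty_constraints(
    pr, ms, selection_config(exclude_heteroatoms = TRUE),
    known_coformers = "benzene", backend = be)
  expect_setequal(out2$pair_id, pr$pair_id[c(1, 3)])
  expect_identical(out2$has_known_cocrystals, c(TRUE, TRUE))
  # fixed co-former search: novelty judged on the partner
  out3 <- apply_novelty_constraints(
    pr, ms, selection_config(fixed_coformer = "pyrene"),
    known_coformers = c("pyrene", "benzene"), backend = be)
  expect_identical(nrow(out3), 2L)
  # partners are benzene (known) and dca (novel), in input order
  expect_identical(out3$has_known_cocrystals, c(TRUE, FALSE))
})
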