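# Shared test helpers: a cross-file cache for expensive fixtures and a
# couple of small builders. Everything is generated in code; no stored
# fixtures.

.oc_test_cache <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

cached <- function(key, expr) {
  if (!exists(key, envir = .oc_test_cache))
    assign(key, force(expr), envir = .oc_test_cache)
  get(key, envir = .oc_test_cache)
}

chem <- function() cached("backend", rdkit_chem_backend())

# small, fast fixture bundle shared across test files
small_fixture <- function(seed = 42L) {
  cached(paste0("fx_", seed), {
    spec <- fixture_spec(n_molecules = 80L, n_descriptors = 30L,
                         n_complementary = 5L, n_correlated_block = 3L,
                         n_constant = 1L, n_labelled_pairs = 150L,
                         seed = seed)
    generate_fixture(spec, n_candidates = 80L)
  })
}

# featurized view of the small fixture (selected features, scaled)
small_featurized <- function(seed = 42L) {
  cached(paste0("feat_", seed), {
    fx <- small_fixture(seed)
    D <- fx$molecules$molecules$descriptors
    lab <- unique(c(fx$labelled$pairs$mol_a, fx$labelled$pairs$mol_b))
    kept <- prune_descriptors(D[lab, ])
    sel <- select_complementary_features(
      D[fx$labelled$pairs$mol_a, kept], D[fx$labelled$pairs$mol_b, kept])
    feats <- kept[sel$kept]
    scaler <- suppressWarnings(fit_minmax_scaler(D[lab, ]))
    S <- scale_features(scaler, D)
    rownames(S) <- rownames(D)
    list(fx = fx, S = S, feats = feats,
         Xl = build_pair_vectors(fx$labelled$pairs, S[, feats], TRUE),
         Xc = build_pair_vectors(fx$candidates$pairs, S[, feats], TRUE))
  })
}

# deterministic toy fingerprints (logical matrix) from integer bit lists
toy_fp <- function(bits, nbits = 8L) {
  fp <- matrix(FALSE, length(bits), nbits)
  for (i in seq_along(bits)) fp[i, bits[[i]]] <- TRUE
  fp
}

expect_setequal_int <- function(a, b) testthat::expect_setequal(as.integer(a),
                                                                as.integer(b))
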