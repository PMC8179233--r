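# Dataset assembly: multi-component SMILES parsing, filters, similarity
# search, pair enumeration.

test_that("multi-component SMILES parse: canonicalization, multiplicity, ratio", {
  be <- chem()
  # two distinct components, one each -> a 1:1 pair
  p <- parse_multicomponent_smiles(
    "c1cc2ccc3cccc4ccc(c1)c2c34.N#CC(C#N)=C1CCC(CC1)C(C#N)C#N", be)
  expect_length(p$components, 2L)
  expect_true(all(p$counts == 1L))
  expect_identical(p$ratio, "1:1")
  expect_true(p$is_pair)
  # single component is flagged not-a-pair
  p1 <- parse_multicomponent_smiles("c1ccccc1", be)
  expect_false(p1$is_pair)
  expect_identical(p1$ratio, "other")
  # canonical duplicates merge with multiplicity
  p2 <- parse_multicomponent_smiles("C.C.O", be)
  expect_identical(sort(unname(p2$counts)), c(1L, 2L))
  expect_identical(p2$ratio, "other")
  expect_true(p2$is_pair)
  # non-canonical spellings of the same molecule merge too
  p3 <- parse_multicomponent_smiles("C1=CC=CC=C1.c1ccccc1", be)
  expect_length(p3$components, 1L)
  expect_identical(unname(p3$counts), 2L)
  # errors
  expect_error(parse_multicomponent_smiles("", be), class = "oc_input_error")
  expect_error(parse_multicomponent_smiles("c1ccccc1.xx(", be),
               class = "oc_parse_error")
})

test_that("parse -> serialize -> parse round-trips component multisets", {
  be <- chem()
  entries <- c("C.C.O", "c1ccccc1.CC#N", "c1ccc2ccccc2c1.c1ccccc1.c1ccccc1")
  for (e in entries) {
    p <- parse_multicomponent_smiles(e, be)
    p2 <- parse_multicomponent_smiles(serialize_multicomponent_smiles(p), be)
    expect_identical(p$counts[order(names(p$counts))],
                     p2$counts[order(names(p2$counts))])
  }
})

test_that("acidic-hydrogen filter keeps aromatics, drops donors, is idempotent", {
  be <- chem()
  ms <- molecule_set(
    c("benzene", "acetic", "phenol", "pyrrole", "naphthalene"),
    c("c1ccccc1", "CC(=O)O", "Oc1ccccc1", "c1cc[nH]c1", "c1ccc2ccccc2c1"))
  out <- filter_acidic_hydrogens(ms, filter_config(), be)
  expect_identical(out$table$mol_id, c("benzene", "naphthalene"))
  # idempotent
  out2 <- filter_acidic_hydrogens(out, filter_config(), be)
  expect_identical(out2$table, out$table)
  # empty input passes through
  empty <- filter_acidic_hydrogens(
    molecule_set(character(0), character(0)), filter_config(), be)
  expect_length(empty, 0L)
})

test_that("solvent-pair filter drops non-aromatic solvents, keeps benzene", {
  be <- chem()
  ms <- molecule_set(c("pyrene", "water", "benzene"),
                     c("c1cc2ccc3cccc4ccc(c1)c2c34", "O", "c1ccccc1"))
  pr <- pair_set(c("pyrene", "pyrene"), c("water", "benzene"))
  out <- filter_solvent_pairs(pr, ms, filter_config(), be)
  expect_identical(out$pair_id, ocscreen:::pair_id_of("pyrene", "benzene"))
  # idempotent; empty in -> empty out
  expect_identical(filter_solvent_pairs(out, ms, filter_config(), be), out)
  expect_identical(nrow(filter_solvent_pairs(out[0, ], ms, filter_config(),
                                             be)), 0L)
  # dangling reference is an error
  bad <- pair_set("pyrene", "ghost")
  expect_error(filter_solvent_pairs(bad, ms, filter_config(), be),
               class = "oc_reference_error")
})

test_that("Tanimoto similarity matches the brute-force oracle on toy fingerprints", {
  oracle <- function(a, b) {
    inter <- sum(a & b); uni <- sum(a | b)
    if (uni == 0) 0 else inter / uni
  }
  set.seed(11)
  for (rep in 1:5) {
    fq <- matrix(runif(6 * 16) < 0.4, 6, 16)
    fd <- matrix(runif(9 * 16) < 0.4, 9, 16)
    got <- tanimoto_similarity(fq, fd)
    want <- outer(seq_len(6), seq_len(9),
                  Vectorize(function(i, j) oracle(fq[i, ], fd[j, ])))
    expect_equal(got, want, tolerance = 1e-12)
  }
  # identity and symmetry
  f <- toy_fp(list(c(1, 3), c(2, 5, 7)))
  expect_equal(diag(tanimoto_similarity(f, f)), c(1, 1))
  expect_equal(tanimoto_similarity(f, f), t(tanimoto_similarity(f, f)))
  expect_error(tanimoto_similarity(matrix(TRUE, 1, 4), matrix(TRUE, 1, 5)),
               class = "oc_input_error")
})

test_that("similarity search retains identity, strict threshold, dedup", {
  q <- molecule_set("q1", "CC", fingerprints = toy_fp(list(c(1, 2, 3))))
  db <- molecule_set(c("a", "b", "c"), c("CC", "CCC", "O"),
                     fingerprints = toy_fp(list(c(1, 2, 3),   # identical, sim 1
                                                c(1, 2, 8),   # sim 0.5
                                                c(6, 7))))    # disjoint, sim 0
  out <- similarity_search(q, db, filter_config(tanimoto_threshold = 0.35))
  expect_identical(out$table$mol_id, c("a", "b"))
  # strictly greater: threshold at 0.5 excludes the 0.5 match
  out2 <- similarity_search(q, db, filter_config(tanimoto_threshold = 0.5))
  expect_identical(out2$table$mol_id, "a")
  expect_error(similarity_search(q, molecule_set("x", "C"), filter_config()),
               class = "oc_input_error")
})

test_that("candidate pair enumeration is exactly n(n-1)/2, each pair once", {
  for (n in c(0L, 1L, 2L, 4L, 9L)) {
    ids <- sprintf("m%02d", seq_len(n))
    pr <- enumerate_candidate_pairs(ids)
    expect_identical(nrow(pr), as.integer(n * (n - 1) / 2))
    expect_false(anyDuplicated(pr$pair_id) > 0)
    expect_true(all(pr$mol_a < pr$mol_b))
    if (n == 4L) {   # brute force over all index pairs
      want <- sort(apply(t(utils::combn(ids, 2)), 1,
                         function(r) ocscreen:::pair_id_of(r[1], r[2])))
      expect_identical(sort(pr$pair_id), want)
    }
  }
  expect_error(enumerate_candidate_pairs(c("a", "a")),
               class = "oc_input_error")
})

test_that("pair records are unordered and reject self-pairs", {
  p1 <- pair_set("b", "a")
  p2 <- pair_set("a", "b")
  expect_identical(p1$pair_id, p2$pair_id)
  expect_identical(p1$mol_a, "a")
  # stoichiometric counts follow the swap
  p3 <- pair_set("b", "a", count_a = 2L, count_b = 1L)
  expect_identical(p3$count_a, 1L)
  expect_identical(p3$count_b, 2L)
  expect_error(pair_set("a", "a"), class = "oc_input_error")
  expect_error(pair_set("a", "b", count_a = 0L), class = "oc_input_error")
})

test_that("labelled-dataset assembly: dedup, filters, drop log", {
  be <- chem()
  entries <- data.frame(
    refcode = c("AAA", "BBB", "CCC", "DDD", "EEE", "FFF"),
    smiles = c(
      "c1ccc2ccccc2c1.c1ccccc1",            # naphthalene + benzene: keep
      "c1ccccc1.c1ccc2ccccc2c1",            # same pair, other order: dup
      "c1ccc2ccccc2c1.CC(=O)O",             # acetic acid: acidic-H drop
      "c1ccc2ccccc2c1.O",                   # water: solvent drop
      "c1ccccc1",                           # single component
      "c1ccc2ccccc2c1.c1ccc2cc3ccccc3cc2c1.O"), # three components
    stringsAsFactors = FALSE)
  out <- assemble_labelled_dataset(entries, filter_config(), be)
  expect_identical(nrow(out$pairs), 1L)
  expect_identical(out$pairs$source_refcode, "AAA")
  expect_identical(unname(out$log["not_two_components"]), 2L)
  expect_identical(unname(out$log["duplicate_pairs"]), 1L)
  expect_identical(unname(out$log["acidic_hydrogen_pairs"]), 1L)
  expect_identical(unname(out$log["solvent_pairs"]), 1L)
  # surviving molecule set covers exactly the surviving pairs
  expect_setequal(out$molecules$table$mol_id,
                  c(out$pairs$mol_a, out$pairs$mol_b))
})

test_that("smi files round-trip through read_smi/write_smi", {
  path <- withr::local_tempfile(fileext = ".smi")
  ms <- molecule_set(c("bz", "np"), c("c1ccccc1", "c1ccc2ccccc2c1"))
  write_smi(ms, path)
  back <- read_smi(path)
  expect_identical(back$table$mol_id, ms$table$mol_id)
  expect_identical(back$table$smiles, ms$table$smiles)
})
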