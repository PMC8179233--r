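# Labelled and candidate dataset assembly.
#
# A co-crystal entry arrives as one multi-component SMILES (components
# separated by '.'); the labelled dataset is the set of such entries that
# survive the acidic-hydrogen and non-aromatic-solvent filters, and the
# candidate dataset is every unordered pair of a screened molecule list.

#' Construct a molecule set
#'
#' The package's container for molecules: an id/SMILES table plus optional
#' per-molecule descriptor and fingerprint matrices, row-aligned with the
#' table.
#'
#' @param mol_id Character vector of unique molecule identifiers.
#' @param smiles Character vector of single-component SMILES (one per id).
#' @param descriptors Optional numeric matrix (one row per molecule).
#' @param fingerprints Optional logical matrix (one row per molecule).
#' @param source `"labelled"` or `"candidate"`.
#' @return An object of class `molecule_set`.
#' @export
molecule_set <- function(mol_id, smiles, descriptors = NULL,
                         fingerprints = NULL,
                         source = c("labelled", "candidate")) {
  source <- match.arg(source)
  mol_id <- as.character(mol_id)
  if (anyDuplicated(mol_id))
    oc_stop("duplicate mol_ids in molecule_set", "oc_input_error")
  if (length(smiles) != length(mol_id))
    oc_stop("smiles and mol_id lengths differ", "oc_input_error")
  for (m in list(descriptors, fingerprints))
    if (!is.null(m) && nrow(m) != length(mol_id))
      oc_stop("matrix rows must align with mol_id", "oc_input_error")
  if (!is.null(descriptors)) {
    descriptors <- as.matrix(descriptors)
    rownames(descriptors) <- mol_id
  }
  if (!is.null(fingerprints)) {
    fingerprints <- as.matrix(fingerprints)
    rownames(fingerprints) <- mol_id
  }
  structure(list(
    table = data.frame(mol_id = mol_id, smiles = as.character(smiles),
                       source = rep_len(source, length(mol_id)),
                       stringsAsFactors = FALSE),
    descriptors = descriptors,
    fingerprints = fingerprints), class = "molecule_set")
}

#' @export
print.molecule_set <- function(x, ...) {
  cat(sprintf("<molecule_set: %d molecules (%s)%s%s>\n",
              nrow(x$table), x$table$source[1] %||% "empty",
              if (!is.null(x$descriptors))
                sprintf(", %d descriptors", ncol(x$descriptors)) else "",
              if (!is.null(x$fingerprints))
                sprintf(", %d-bit fingerprints", ncol(x$fingerprints)) else ""))
  invisible(x)
}

#' @export
length.molecule_set <- function(x) nrow(x$table)

subset_molecules <- function(mols, keep) {
  structure(list(
    table = mols$table[keep, , drop = FALSE],
    descriptors = if (!is.null(mols$descriptors))
      mols$descriptors[keep, , drop = FALSE],
    fingerprints = if (!is.null(mols$fingerprints))
      mols$fingerprints[keep, , drop = FALSE]), class = "molecule_set")
}

#' Construct a pair record table
#'
#' Unordered identity: `(a, b)` and `(b, a)` are the same record; members
#' are stored sorted and `pair_id` is `"a|b"` with `a <= b`.
#'
#' @param mol_a,mol_b Character vectors of member molecule ids.
#' @param label `"known_cocrystal"` or `"candidate"` (recycled).
#' @param count_a,count_b Stoichiometric multiplicities (default 1).
#' @param source_refcode Optional provenance strings.
#' @return A data.frame of class `pair_set` with columns `pair_id`,
#'   `mol_a`, `mol_b`, `count_a`, `count_b`, `label`, `source_refcode`.
#' @export
pair_set <- function(mol_a, mol_b, label = "candidate",
                     count_a = 1L, count_b = 1L, source_refcode = NA_character_) {
  mol_a <- as.character(mol_a); mol_b <- as.character(mol_b)
  if (any(mol_a == mol_b))
    oc_stop("self-pairs (A,A) are not valid pair records", "oc_input_error")
  n <- length(mol_a)
  label <- rep_len(label, n)
  if (!all(label %in% c("known_cocrystal", "candidate")))
    oc_stop("label must be 'known_cocrystal' or 'candidate'", "oc_input_error")
  count_a <- rep_len(as.integer(count_a), n)
  count_b <- rep_len(as.integer(count_b), n)
  if (any(count_a < 1L) || any(count_b < 1L))
    oc_stop("stoichiometric counts must be positive integers", "oc_input_error")
  swap <- mol_a > mol_b
  df <- data.frame(
    pair_id = pair_id_of(mol_a, mol_b),
    mol_a = ifelse(swap, mol_b, mol_a),
    mol_b = ifelse(swap, mol_a, mol_b),
    count_a = ifelse(swap, count_b, count_a),
    count_b = ifelse(swap, count_a, count_b),
    label = label,
    source_refcode = rep_len(as.character(source_refcode), n),
    stringsAsFactors = FALSE)
  class(df) <- c("pair_set", "data.frame")
  df
}

#' Filtering configuration for dataset assembly
#'
#' @param acidic_h_smarts SMARTS patterns whose match excludes a molecule
#'   (default: carboxylic acids, phenols, N-H donors).
#' @param nonaromatic_solvent_smiles SMILES of common non-aromatic solvents
#'   whose presence excludes a pair; defaults to the editable resource in
#'   `inst/extdata/nonaromatic_solvents.smi`.
#' @param tanimoto_threshold Similarity-search threshold (strictly greater
#'   than; default 0.35).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(acidic_h_smarts = default_acidic_smarts(),
                          nonaromatic_solvent_smiles = default_solvent_list(),
                          tanimoto_threshold = 0.35) {
  check_scalar(tanimoto_threshold, 0, 1)
  structure(list(acidic_h_smarts = acidic_h_smarts,
                 nonaromatic_solvent_smiles = nonaromatic_solvent_smiles,
                 tanimoto_threshold = tanimoto_threshold),
            class = "filter_config")
}

#' Default acidic-hydrogen SMARTS patterns
#' @return Named character vector (carboxylic acid, phenol, N-H donor).
#' @export
default_acidic_smarts <- function() {
  c(carboxylic_acid = "[CX3](=O)[OX2H1]",
    phenol = "c[OX2H1]",
    nh_donor = "[#7;!H0]")
}

#' Default non-aromatic solvent list
#'
#' Shipped as a plain-text resource so it can be edited without touching
#' code; one SMILES + name per line.
#' @return Character vector of SMILES.
#' @export
default_solvent_list <- function() {
  path <- system.file("extdata", "nonaromatic_solvents.smi",
                      package = "ocscreen")
  if (path == "") path <- file.path("inst", "extdata",
                                    "nonaromatic_solvents.smi")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  vapply(strsplit(lines, "[[:space:]]+"), `[[`, character(1), 1L)
}

#' Parse a multi-component SMILES entry
#'
#' Splits an entry at the component separator `.`, canonicalizes each
#' component, merges identical components with multiplicity, and
#' classifies the stoichiometry: `"1:1"` iff exactly two distinct
#' components each appearing once, otherwise `"other"`. Entries with a
#' number of distinct components different from two are flagged as not
#' usable for the pair dataset.
#'
#' @param entry One multi-component SMILES string.
#' @param backend A `chem_backend` used for canonicalization.
#' @return A list with `components` (canonical SMILES of distinct
#'   components), `counts` (named integer multiplicities), `ratio`
#'   (`"1:1"` or `"other"`) and `is_pair` (logical).
#' @export
parse_multicomponent_smiles <- function(entry,
                                        backend = default_chem_backend()) {
  if (!is.character(entry) || length(entry) != 1L || !nzchar(trimws(entry)))
    oc_stop("entry must be one non-empty SMILES string", "oc_input_error")
  parts <- strsplit(trimws(entry), ".", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0L)
    oc_stop("entry contains no components", "oc_input_error")
  canon <- canonicalize_smiles(backend, parts)
  counts <- table(canon)
  components <- names(counts)
  counts <- stats::setNames(as.integer(counts), components)
  ratio <- if (length(components) == 2L && all(counts == 1L)) "1:1" else "other"
  list(components = components, counts = counts, ratio = ratio,
       is_pair = length(components) == 2L)
}

#' Serialize parsed components back to a multi-component SMILES
#'
#' Inverse of [parse_multicomponent_smiles()] up to component order:
#' repeats each component by its multiplicity and joins with `.`.
#'
#' @param parsed The list returned by [parse_multicomponent_smiles()].
#' @return A single SMILES string.
#' @export
serialize_multicomponent_smiles <- function(parsed) {
  paste(rep(names(parsed$counts), parsed$counts), collapse = ".")
}

#' Remove molecules with acidic hydrogens
#'
#' Keeps exactly the molecules matching none of the configured SMARTS
#' patterns, preserving input order. With strong hydrogen-bond donors
#' removed, the remaining co-crystals are held together predominantly by
#' pi-pi stacking.
#'
#' @param molecules A `molecule_set`.
#' @param cfg A [filter_config()].
#' @param backend A `chem_backend`.
#' @return The filtered `molecule_set`.
#' @export
filter_acidic_hydrogens <- function(molecules, cfg = filter_config(),
                                    backend = default_chem_backend()) {
  stopifnot(inherits(molecules, "molecule_set"))
  if (nrow(molecules$table) == 0L) return(molecules)
  hit <- match_smarts(backend, molecules$table$smiles, cfg$acidic_h_smarts)
  subset_molecules(molecules, !hit)
}

#' Drop pairs containing a common non-aromatic solvent
#'
#' Pairs with a member on the configured non-aromatic solvent list are
#' excluded; aromatic solvents (benzene, toluene) are kept because their
#' interactions are still pi-pi stacking.
#'
#' @param pairs A `pair_set`.
#' @param molecules The `molecule_set` the pairs refer to.
#' @param cfg A [filter_config()].
#' @param backend A `chem_backend` (canonicalizes the solvent list so list
#'   entries and molecule SMILES compare in the same dialect).
#' @return The filtered `pair_set`.
#' @export
filter_solvent_pairs <- function(pairs, molecules, cfg = filter_config(),
                                 backend = default_chem_backend()) {
  stopifnot(inherits(pairs, "pair_set"), inherits(molecules, "molecule_set"))
  if (nrow(pairs) == 0L) return(pairs)
  ids <- molecules$table$mol_id
  missing <- setdiff(unique(c(pairs$mol_a, pairs$mol_b)), ids)
  if (length(missing) > 0L)
    oc_stop(paste("pairs reference unknown mol_ids:",
                  paste(missing, collapse = ", ")), "oc_reference_error")
  solvents <- unique(canonicalize_smiles(backend,
                                         cfg$nonaromatic_solvent_smiles))
  smiles_of <- stats::setNames(canonicalize_smiles(backend,
                                                   molecules$table$smiles), ids)
  bad <- smiles_of[pairs$mol_a] %in% solvents |
    smiles_of[pairs$mol_b] %in% solvents
  out <- pairs[!bad, , drop = FALSE]
  class(out) <- c("pair_set", "data.frame")
  out
}

#' Tanimoto similarity between fingerprint matrices
#'
#' `|a AND b| / |a OR b|` for every query/database row combination. The
#' similarity of two all-zero fingerprints is defined as 0.
#'
#' @param fp_query,fp_db Logical matrices with equal column counts.
#' @return Numeric matrix, `nrow(fp_query)` x `nrow(fp_db)`.
#' @export
tanimoto_similarity <- function(fp_query, fp_db) {
  fp_query <- as.matrix(fp_query) * 1; fp_db <- as.matrix(fp_db) * 1
  if (ncol(fp_query) != ncol(fp_db))
    oc_stop("fingerprint lengths differ", "oc_input_error")
  inter <- tcrossprod(fp_query, fp_db)
  uni <- outer(rowSums(fp_query), rowSums(fp_db), "+") - inter
  sim <- inter / uni
  sim[uni == 0] <- 0
  sim
}

#' Fingerprint similarity search
#'
#' Returns the database molecules whose Tanimoto similarity to at least
#' one query molecule is strictly greater than the configured threshold,
#' deduplicated by `mol_id`. This is the screening step that narrows a
#' purchasable-molecule catalogue down to candidates resembling a small
#' representative set of extended polyaromatic molecules.
#'
#' @param queries,database `molecule_set`s carrying fingerprints.
#' @param cfg A [filter_config()] (`tanimoto_threshold` is used).
#' @return The retained subset of `database`.
#' @export
similarity_search <- function(queries, database, cfg = filter_config()) {
  stopifnot(inherits(queries, "molecule_set"),
            inherits(database, "molecule_set"))
  if (is.null(queries$fingerprints) || is.null(database$fingerprints))
    oc_stop("similarity_search needs fingerprints on both sets",
            "oc_input_error")
  sim <- tanimoto_similarity(queries$fingerprints, database$fingerprints)
  keep <- apply(sim, 2, max) > cfg$tanimoto_threshold
  subset_molecules(database, keep)
}

#' Enumerate all unordered candidate pairs
#'
#' All `n (n - 1) / 2` pairs of distinct molecules, each exactly once,
#' labelled `"candidate"`. Self-pairs are excluded.
#'
#' @param molecules A `molecule_set` (or a character vector of unique ids).
#' @return A `pair_set`.
#' @export
enumerate_candidate_pairs <- function(molecules) {
  ids <- if (inherits(molecules, "molecule_set")) molecules$table$mol_id
  else as.character(molecules)
  if (anyDuplicated(ids))
    oc_stop("duplicate mol_ids", "oc_input_error")
  n <- length(ids)
  if (n < 2L)
    return(pair_set(character(0), character(0))[0, , drop = FALSE])
  idx <- utils::combn(n, 2L)
  pair_set(ids[idx[1, ]], ids[idx[2, ]], label = "candidate")
}

#' Read a .smi file (one SMILES + optional id per line)
#'
#' Lines are whitespace-separated: SMILES first, optional identifier
#' second; `#` comment lines and blanks are skipped. Missing ids are
#' generated.
#'
#' @param path File path.
#' @param source `"labelled"` or `"candidate"`.
#' @return A `molecule_set` (without descriptors or fingerprints).
#' @export
read_smi <- function(path, source = "candidate") {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[[:space:]]+")
  smiles <- vapply(parts, `[[`, character(1), 1L)
  ids <- vapply(seq_along(parts), function(i)
    if (length(parts[[i]]) > 1L) parts[[i]][[2L]] else sprintf("mol%04d", i),
    character(1))
  molecule_set(ids, smiles, source = source)
}

#' Write a molecule set to a .smi file
#' @param molecules A `molecule_set`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_smi <- function(molecules, path) {
  stopifnot(inherits(molecules, "molecule_set"))
  writeLines(paste(molecules$table$smiles, molecules$table$mol_id),
             path)
  invisible(path)
}

#' Assemble the labelled pair dataset from multi-component SMILES entries
#'
#' Parses each entry, keeps the two-component ones, deduplicates pairs
#' by canonical component multiset, applies the acidic-hydrogen and
#' non-aromatic-solvent filters, and reports what every step dropped.
#'
#' @param entries A data.frame with columns `smiles` (multi-component)
#'   and optionally `refcode`.
#' @param cfg A [filter_config()].
#' @param backend A `chem_backend`.
#' @return A list: `molecules` (a labelled `molecule_set`), `pairs` (a
#'   `pair_set` with stoichiometric counts and refcodes), `log` (named
#'   integer vector of drop counts per step).
#' @export
assemble_labelled_dataset <- function(entries, cfg = filter_config(),
                                      backend = default_chem_backend()) {
  stopifnot(is.data.frame(entries), "smiles" %in% names(entries))
  refcodes <- entries$refcode %||% rep(NA_character_, nrow(entries))
  parsed <- lapply(entries$smiles, parse_multicomponent_smiles,
                   backend = backend)
  is_pair <- vapply(parsed, `[[`, logical(1), "is_pair")
  log <- c(not_two_components = sum(!is_pair))
  parsed <- parsed[is_pair]; refcodes <- refcodes[is_pair]
  # molecule table keyed by canonical SMILES
  all_smiles <- unique(unlist(lapply(parsed, `[[`, "components")))
  mol_ids <- stats::setNames(sprintf("M%04d", seq_along(all_smiles)),
                             all_smiles)
  pairs <- do.call(rbind, lapply(seq_along(parsed), function(i) {
    p <- parsed[[i]]
    pair_set(mol_ids[[p$components[1]]], mol_ids[[p$components[2]]],
             label = "known_cocrystal",
             count_a = p$counts[[p$components[1]]],
             count_b = p$counts[[p$components[2]]],
             source_refcode = refcodes[i])
  }))
  dup <- duplicated(pairs$pair_id)
  log["duplicate_pairs"] <- sum(dup)
  pairs <- pairs[!dup, , drop = FALSE]
  class(pairs) <- c("pair_set", "data.frame")
  molecules <- molecule_set(unname(mol_ids), all_smiles, source = "labelled")
  kept_mols <- filter_acidic_hydrogens(molecules, cfg, backend)
  dropped_ids <- setdiff(molecules$table$mol_id, kept_mols$table$mol_id)
  log["acidic_hydrogen_molecules"] <- length(dropped_ids)
  bad_pair <- pairs$mol_a %in% dropped_ids | pairs$mol_b %in% dropped_ids
  log["acidic_hydrogen_pairs"] <- sum(bad_pair)
  pairs <- pairs[!bad_pair, , drop = FALSE]
  class(pairs) <- c("pair_set", "data.frame")
  n_before <- nrow(pairs)
  pairs <- filter_solvent_pairs(pairs, kept_mols, cfg, backend)
  log["solvent_pairs"] <- n_before - nrow(pairs)
  used <- unique(c(pairs$mol_a, pairs$mol_b))
  molecules <- subset_molecules(kept_mols,
                                kept_mols$table$mol_id %in% used)
  list(molecules = molecules, pairs = pairs, log = log)
}
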