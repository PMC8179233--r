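# Pluggable chemistry backend.
#
# All structure-aware operations (canonical SMILES, SMARTS substructure
# matching, circular fingerprints, ring statistics) go through a backend
# object so the rest of the package never touches a SMILES string directly.
# The default backend shells out to RDKit (batch JSON over a subprocess);
# a degraded pure-R backend exists so that descriptor-only workflows run
# where no interpreter is available.

#' Chemistry backend based on RDKit
#'
#' Returns a backend object whose methods delegate to a bundled Python
#' helper script (`inst/python/chemtool.py`). All calls are batched: one
#' subprocess per call, any number of molecules.
#'
#' @param python Path to the python interpreter (default `"python"` on PATH).
#' @return An object of class `chem_backend`.
#' @seealso [null_chem_backend()] for the structure-blind fallback.
#' @export
rdkit_chem_backend <- function(python = "python") {
  script <- system.file("python", "chemtool.py", package = "ocscreen")
  if (script == "")
    script <- file.path("inst", "python", "chemtool.py")
  structure(list(name = "rdkit", python = python, script = script),
            class = "chem_backend")
}

#' Structure-blind fallback backend
#'
#' Canonicalization is the identity, fingerprints are hashes of the SMILES
#' string, and SMARTS matching or ring queries raise an error. Only useful
#' when molecules are opaque labels and all information lives in the
#' descriptor tables.
#'
#' @return An object of class `chem_backend`.
#' @export
null_chem_backend <- function() {
  structure(list(name = "null"), class = "chem_backend")
}

#' Is RDKit reachable through the python on PATH?
#' @param python Path to the python interpreter.
#' @return `TRUE` or `FALSE`.
#' @export
rdkit_available <- function(python = "python") {
  ok <- suppressWarnings(tryCatch(
    system2(python, c("-c", "import rdkit"), stdout = FALSE, stderr = FALSE),
    error = function(e) 1L))
  identical(ok, 0L)
}

#' Default chemistry backend
#'
#' RDKit when importable, otherwise the structure-blind fallback
#' (with a message).
#' @return A `chem_backend` object.
#' @export
default_chem_backend <- function() {
  if (rdkit_available()) rdkit_chem_backend() else {
    message("RDKit not reachable; using the structure-blind chemistry backend")
    null_chem_backend()
  }
}

chem_call <- function(backend, op, payload) {
  stopifnot(inherits(backend, "chem_backend"))
  if (backend$name != "rdkit")
    oc_stop(sprintf("operation '%s' needs the rdkit backend", op),
            "oc_backend_error")
  req <- jsonlite::toJSON(c(list(op = op), payload), auto_unbox = TRUE,
                          null = "null", digits = NA)
  infile <- tempfile(fileext = ".json")
  on.exit(unlink(infile))
  writeLines(req, infile)
  # RDKit chatters parse diagnostics on stderr; failures come back as
  # structured JSON, so stderr is discarded
  out <- suppressWarnings(system2(backend$python, c(backend$script),
                                  stdin = infile, stdout = TRUE,
                                  stderr = FALSE))
  res <- tryCatch(jsonlite::fromJSON(paste(out, collapse = ""),
                                     simplifyVector = FALSE),
                  error = function(e)
                    oc_stop(paste("chemistry backend produced no JSON:",
                                  paste(utils::tail(out, 3), collapse = " ")),
                            "oc_backend_error"))
  if (!is.null(res$error)) oc_stop(res$error, "oc_backend_error")
  res
}

#' Canonicalize SMILES strings
#'
#' @param backend A `chem_backend`.
#' @param smiles Character vector of single-component SMILES.
#' @return Character vector of canonical SMILES.
#' @export
canonicalize_smiles <- function(backend, smiles) {
  if (length(smiles) == 0L) return(character(0))
  if (backend$name == "null") return(as.character(smiles))
  res <- chem_call(backend, "canonicalize", list(smiles = as.list(unname(smiles))))
  out <- vapply(res$canonical, function(x) if (is.null(x)) NA_character_ else x,
                character(1))
  if (anyNA(out))
    oc_stop(paste("unparsable SMILES:",
                  paste(smiles[is.na(out)], collapse = ", ")),
            "oc_parse_error", offending = smiles[is.na(out)])
  out
}

#' Match molecules against a set of SMARTS patterns
#'
#' @param backend A `chem_backend`.
#' @param smiles Character vector of SMILES.
#' @param patterns Character vector of SMARTS; a molecule matches if any
#'   pattern has a substructure hit.
#' @return Logical vector, one element per molecule.
#' @export
match_smarts <- function(backend, smiles, patterns) {
  if (length(patterns) == 0L)
    oc_stop("empty SMARTS pattern list", "oc_config_error")
  if (length(smiles) == 0L) return(logical(0))
  res <- chem_call(backend, "smarts_match",
                   list(smiles = as.list(unname(smiles)), patterns = as.list(unname(patterns))))
  vapply(res$match, function(x) if (is.null(x)) NA else x, logical(1))
}

#' Circular (Morgan) fingerprints
#'
#' @param backend A `chem_backend`.
#' @param smiles Character vector of SMILES.
#' @param nbits Fingerprint length in bits.
#' @param radius Morgan radius (2 corresponds to ECFP4).
#' @return A logical matrix, one row per molecule, `nbits` columns.
#' @export
morgan_fingerprint <- function(backend, smiles, nbits = 1024L, radius = 2L) {
  n <- length(smiles)
  fp <- matrix(FALSE, n, nbits)
  if (n == 0L) return(fp)
  if (backend$name == "null") {
    # hash character trigrams of the raw string; structure-blind but stable
    for (i in seq_len(n)) {
      s <- smiles[[i]]
      grams <- substring(s, seq_len(max(nchar(s) - 2, 1)),
                         seq_len(max(nchar(s) - 2, 1)) + 2)
      idx <- (vapply(grams, function(g)
        sum(utf8ToInt(g) * c(1L, 31L, 961L)[seq_len(nchar(g))]),
        numeric(1)) %% nbits) + 1
      fp[i, unique(idx)] <- TRUE
    }
    return(fp)
  }
  res <- chem_call(backend, "fingerprint",
                   list(smiles = as.list(unname(smiles)), nbits = nbits,
                        radius = radius))
  for (i in seq_len(n)) {
    bits <- res$onbits[[i]]
    if (is.null(bits))
      oc_stop(paste("unparsable SMILES:", smiles[[i]]), "oc_parse_error")
    fp[i, unlist(bits) + 1L] <- TRUE
  }
  fp
}

#' Ring statistics used by solvent heuristics and novelty constraints
#'
#' @param backend A `chem_backend`.
#' @param smiles Character vector of SMILES.
#' @return A data.frame with columns `n_rings`, `n_aromatic_rings`,
#'   `heavy_atoms`, `n_substituents` (ring atoms bonded to out-of-ring
#'   heavy atoms) and `has_heteroatom`.
#' @export
ring_info <- function(backend, smiles) {
  if (length(smiles) == 0L)
    return(data.frame(n_rings = integer(0), n_aromatic_rings = integer(0),
                      heavy_atoms = integer(0), n_substituents = integer(0),
                      has_heteroatom = logical(0)))
  res <- chem_call(backend, "ring_info", list(smiles = as.list(unname(smiles))))
  rows <- lapply(res$info, function(x) {
    if (is.null(x)) oc_stop("unparsable SMILES in ring_info", "oc_parse_error")
    as.data.frame(x)
  })
  do.call(rbind, rows)
}

#' Tanimoto similarity of molecules to one reference molecule
#'
#' Computed on Morgan fingerprints by the backend; used for the
#' reference-similarity objective in Pareto selection.
#'
#' @param backend A `chem_backend`.
#' @param smiles Character vector of SMILES.
#' @param reference A single reference SMILES (e.g. TCNQ).
#' @return Numeric vector of similarities in \[0, 1\].
#' @export
similarity_to_reference <- function(backend, smiles, reference) {
  if (length(smiles) == 0L) return(numeric(0))
  res <- chem_call(backend, "tanimoto_ref",
                   list(smiles = as.list(unname(smiles)), reference = reference))
  vapply(res$similarity, function(x) if (is.null(x)) NA_real_ else x,
         numeric(1))
}
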