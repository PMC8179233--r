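# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a classed condition
#' @noRd
oc_stop <- function(msg, class, ...) {
  stop(structure(class = c(class, "ocscreen_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

#' Check that x is a single finite number in [lo, hi]
#' @noRd
check_scalar <- function(x, lo = -Inf, hi = Inf, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    oc_stop(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi),
            "oc_input_error")
  x
}

#' Pairwise squared Euclidean distances between rows of a and rows of b
#' @noRd
cross_dist2 <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

cross_dist <- function(a, b) sqrt(cross_dist2(a, b))

#' Deterministic integer sub-seed derived from a master seed
#'
#' Keeps every derived seed below 2^31 and reproducible.
#' @noRd
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %% 2147483629) + 1L
}

#' Run a block with a local RNG state
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Canonical unordered pair identifier from two molecule ids
#' @noRd
pair_id_of <- function(a, b) {
  swap <- a > b
  paste(ifelse(swap, b, a), ifelse(swap, a, b), sep = "|")
}
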