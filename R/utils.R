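# Internal helpers: seeded evaluation, deterministic seed derivation, pair indexing.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards.  With seed = NULL the current stream is
# used (and advanced) as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a run seed from a master seed and a tuple of indices
#'
#' Counter-based derivation (multiplicative congruential step per index) so
#' ensemble members get distinct, reproducible, order-independent seeds below
#' 2^31.  Used throughout the experiment drivers: every (substrate, initial
#' configuration, coupling) cell derives its own stream.
#'
#' @param seed master seed (integer)
#' @param ... non-negative integer indices identifying the run
#' @return a single integer seed in [0, 2^31 - 2]
#' @export
#' @examples
#' derive_seed(1, 2, 3) != derive_seed(1, 3, 2)
derive_seed <- function(seed, ...) {
  idx <- c(...)
  stopifnot(length(seed) == 1, is.finite(seed))
  m <- 2147483647
  s <- as.double(seed) %% m
  for (i in idx) {
    stopifnot(is.finite(i), i >= 0)
    s <- (s * 48271 + as.double(i) + 1) %% m
  }
  as.integer(s)
}

# All unordered node pairs (i < j) of an n-node graph, in the fixed link-index
# order used for rank tie-breaking: column-major upper triangle.
link_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  tibble::tibble(node_a = idx[, "row"], node_b = idx[, "col"])
}

# Extract the upper-triangle weight vector in link-index order.
upper_weights <- function(W) W[upper.tri(W)]

stop_if_not_wns <- function(x) {
  if (!inherits(x, "coherence_matrix"))
    stop("expected a `coherence_matrix` (see pairwise_phase_coherence())",
         call. = FALSE)
  invisible(x)
}
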