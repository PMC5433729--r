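#' @useDynLib keycontrib, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbinom rpois runif quantile var sd cor setNames pchisq
#' @importFrom utils head tail read.table write.table
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
# When seed is NULL the current RNG stream is used (and advanced).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive independent substream seeds from a master seed (all < 2^31).
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, as.list(sample.int(.Machine$integer.max - 1L, n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)

# Symmetry check used by every consumer of a relationship matrix.
check_symmetric <- function(G, tol = 1e-8, what = "relationship matrix") {
  stop_if(!is.matrix(G) || nrow(G) != ncol(G),
          what, " must be a square matrix")
  rel <- max(abs(G - t(G))) / max(1, max(abs(G)))
  stop_if(rel > tol, what, " is not symmetric (relative asymmetry ",
          format(rel, digits = 3), ")")
  (G + t(G)) / 2
}

matrix_ids <- function(G) {
  ids <- rownames(G)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(G)))
  ids
}
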