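#' Eigendecomposition of a relationship matrix
#'
#' Full symmetric EVD G = U L U' with eigenvalues sorted descending.
#' Standardized eigenvectors u_i / sqrt(lambda_i) (the coordinate system in
#' which individuals are projected onto components) are available through
#' [standardized_eigenvectors()] for eigenvalues above the tolerance.
#'
#' @param G symmetric relationship matrix (ids as dimnames).
#' @param tol relative tolerance below which eigenvalues are treated as
#'   zero (fraction of the leading eigenvalue).
#' @return list of class `grm_evd`: `values`, `vectors`, `ids`, `tol_abs`.
#' @export
eigendecompose <- function(G, tol = 1e-10) {
  ids <- matrix_ids(G)
  G <- check_symmetric(G)
  e <- eigen(G, symmetric = TRUE)
  structure(list(values = e$values, vectors = e$vectors, ids = ids,
                 tol_abs = tol * max(abs(e$values[1]), .Machine$double.eps)),
            class = "grm_evd")
}

#' @export
print.grm_evd <- function(x, ...) {
  cat("grm_evd:", length(x$values), "eigenvalues, leading =",
      format(x$values[1], digits = 4), "\n")
  invisible(x)
}

#' Standardized eigenvectors
#'
#' Column i is u_i / sqrt(lambda_i), so that s_i' G s_j equals the Kronecker
#' delta for i, j within the leading k components.
#'
#' @param evd a [eigendecompose()] result.
#' @param k number of leading components; all must have eigenvalues above
#'   the decomposition tolerance.
#' @return n x k matrix S.
#' @export
standardized_eigenvectors <- function(evd, k) {
  stopifnot(inherits(evd, "grm_evd"))
  stop_if(k < 1 || k > length(evd$values), "k out of range")
  lam <- evd$values[seq_len(k)]
  stop_if(any(lam <= evd$tol_abs),
          "eigenvalue at or below tolerance within the first k components")
  sweep(evd$vectors[, seq_len(k), drop = FALSE], 2, sqrt(lam), "/")
}

# Fast correlation matrix via BLAS (columns = variables).
cor_fast <- function(X) {
  Xs <- scale(X)
  C <- crossprod(Xs) / (nrow(X) - 1)
  C[C > 1] <- 1
  C[C < -1] <- -1
  C
}

# Marchenko-Pastur inverse CDF on a grid (gamma = n / m_eff), unit mean.
# Integrated in s = sqrt(x), which removes the 1/sqrt(x) edge singularity
# at gamma = 1.
mp_rank_quantiles <- function(n, gamma) {
  a <- (1 - sqrt(gamma))^2
  b <- (1 + sqrt(gamma))^2
  s <- seq(sqrt(a), sqrt(b), length.out = 8192)[-1]
  dens_s <- sqrt(pmax((b - s^2) * (s^2 - a), 0)) / (pi * gamma * s)
  cdf <- cumsum((dens_s[-1] + dens_s[-length(dens_s)]) / 2 * diff(s))
  cdf <- c(0, cdf / cdf[length(cdf)])
  mass1 <- min(1, 1 / gamma)       # gamma > 1: point mass at zero
  pr <- 1 - (seq_len(n) - 0.5) / n # lower-CDF level of rank i
  keep <- pr >= 1 - mass1          # ranks inside the continuous bulk
  q <- numeric(n)
  level <- (pr[keep] - (1 - mass1)) / mass1
  q[keep] <- stats::approx(cdf, s, xout = pmin(pmax(level, 0), 1),
                           rule = 2)$y^2
  q
}

#' Number of significant components by Horn's parallel analysis
#'
#' Compares observed component eigenvalues rank by rank against the
#' (1 - alpha) quantile of eigenvalues obtained from structure-free null
#' data, retaining the leading components that exceed their null quantile.
#'
#' Three null models are available.
#'
#' `"paran"` (default) treats the relationship matrix as a data matrix, as
#' the classic data-based parallel-analysis procedure does: the observed
#' eigenvalues are those of the correlation matrix of G's columns, and each
#' Monte-Carlo replicate draws an n x n standard-normal data matrix and
#' takes the eigenvalues of its column correlation matrix. This asks which
#' components of the relationship *structure* stand out against noise, and
#' is insensitive to the Mendelian-sampling spread of realized
#' relationships within families.
#'
#' `"marchenko"` is the deterministic large-n limit of `"paran"`: rank
#' quantiles of the Marchenko-Pastur law with aspect ratio 1. No Monte
#' Carlo; intended for matrices too large to resample (the significance
#' level does not enter).
#'
#' `"permutation"` compares the eigenvalues of G itself against
#' allele-sharing relationship matrices rebuilt after independently
#' permuting individuals within every SNP (requires genotypes); null
#' eigenvalues are rescaled so the null trace matches the observed trace.
#' This null also promotes real within-family sampling components and
#' typically retains many more components than `"paran"`.
#'
#' @param G symmetric relationship matrix.
#' @param genotypes optional dosage matrix (SNPs x individuals), required
#'   for the permutation null.
#' @param alpha significance level (null quantile 1 - alpha).
#' @param iterations Monte-Carlo iterations for the resampling nulls.
#' @param null `"paran"`, `"marchenko"` or `"permutation"`.
#' @param rule `"prefix"` stops at the first non-significant rank (the
#'   classic sequential retention rule); `"count"` counts all significant
#'   ranks.
#' @param evd optional precomputed [eigendecompose()] result for G (used by
#'   the permutation null only).
#' @param seed optional RNG seed.
#' @return list of class `parallel_analysis`: `k`, `alpha`, `iterations`,
#'   `observed` (the eigenvalues the null is compared against),
#'   `null_quantiles`, `null_mean`, `method`, `rule`.
#' @export
significant_components <- function(G, genotypes = NULL, alpha = 0.01,
                                   iterations = 100,
                                   null = c("paran", "marchenko",
                                            "permutation"),
                                   rule = c("prefix", "count"),
                                   evd = NULL, seed = NULL) {
  null <- match.arg(null)
  rule <- match.arg(rule)
  n <- nrow(G)
  if (null != "marchenko" && iterations < 20)
    warning("fewer than 20 iterations: null quantiles are unstable")

  if (null == "paran") {
    obs <- eigen(cor_fast(G), symmetric = TRUE, only.values = TRUE)$values
    null_ev <- with_seed(seed, {
      vapply(seq_len(iterations), function(it) {
        X <- matrix(stats::rnorm(n * n), n, n)
        eigen(cor_fast(X), symmetric = TRUE, only.values = TRUE)$values
      }, numeric(n))
    })
    qs <- apply(null_ev, 1, quantile, probs = 1 - alpha, names = FALSE)
    null_mean <- rowMeans(null_ev)
  } else if (null == "marchenko") {
    obs <- eigen(cor_fast(G), symmetric = TRUE, only.values = TRUE)$values
    qs <- mp_rank_quantiles(n, 1)
    null_mean <- qs
    iterations <- 0L
  } else {
    obs <- if (!is.null(evd)) evd$values else
      eigen(check_symmetric(G), symmetric = TRUE, only.values = TRUE)$values
    tr_obs <- sum(diag(G))
    stop_if(is.null(genotypes), "permutation null needs genotypes")
    stop_if(ncol(genotypes) != n, "genotypes must cover the matrix individuals")
    p <- rowMeans(genotypes, na.rm = TRUE) / 2
    keep <- p > 0 & p < 1
    X <- t(genotypes[keep, , drop = FALSE]) - rep(2 * p[keep], each = n)
    X[is.na(X)] <- 0
    den <- sum(2 * p[keep] * (1 - p[keep]))
    scale_fac <- tr_obs / (sum(X^2) / den)  # trace is permutation-invariant
    m <- ncol(X)
    null_ev <- with_seed(seed, {
      vapply(seq_len(iterations), function(it) {
        for (j in seq_len(m)) X[, j] <- X[sample.int(n), j]
        Gn <- tcrossprod(X) / den
        eigen(Gn, symmetric = TRUE, only.values = TRUE)$values
      }, numeric(n))
    })
    qs <- apply(null_ev, 1, quantile, probs = 1 - alpha, names = FALSE) *
      scale_fac
    null_mean <- rowMeans(null_ev) * scale_fac
  }

  sig <- obs > qs
  k <- if (rule == "prefix") {
    if (all(sig)) n else which.min(sig) - 1L
  } else sum(sig)
  structure(list(k = as.integer(k), alpha = alpha, iterations = iterations,
                 observed = obs, null_quantiles = qs, null_mean = null_mean,
                 method = null, rule = rule),
            class = "parallel_analysis")
}

#' @export
print.parallel_analysis <- function(x, ...) {
  cat("parallel_analysis:", x$k, "significant components (alpha =", x$alpha,
      ",", x$method, "null,", x$iterations, "iterations)\n")
  invisible(x)
}

#' Genetic contribution scores
#'
#' Projects every individual's relationship profile (column g_j of G) onto
#' the k leading standardized eigenvectors, r_ij = s_i' g_j, and scores each
#' individual by gc_j = sum over i <= k of r_ij squared. Individuals are
#' ranked by gc descending (ties keep input order); the top k are flagged as
#' key contributors.
#'
#' @param G symmetric relationship matrix.
#' @param k number of significant components (see
#'   [significant_components()]).
#' @param evd optional precomputed [eigendecompose()] result.
#' @return list of class `contribution_result`: `r` (k x n), `gc`
#'   (named length-n vector), `k`, `ranking` (ids by gc descending),
#'   `key_contributors` (top-k ids).
#' @export
contribution_scores <- function(G, k, evd = NULL) {
  if (is.null(evd)) evd <- eigendecompose(G)
  stop_if(length(evd$values) != nrow(G), "evd does not match G")
  S <- standardized_eigenvectors(evd, k)
  r <- crossprod(S, G)                     # k x n projections
  gc <- colSums(r^2)
  names(gc) <- evd$ids
  ord <- order(gc, decreasing = TRUE)      # stable: ties keep input order
  structure(list(r = r, gc = gc, k = as.integer(k),
                 ranking = evd$ids[ord],
                 key_contributors = evd$ids[ord[seq_len(k)]]),
            class = "contribution_result")
}

#' @export
print.contribution_result <- function(x, ...) {
  cat("contribution_result: k =", x$k, "; top contributors:",
      paste(head(x$key_contributors, 5), collapse = ", "),
      if (x$k > 5) "..." else "", "\n")
  invisible(x)
}

#' @export
as.data.frame.contribution_result <- function(x, ...) {
  ids <- names(x$gc)
  rank <- match(ids, x$ranking)
  data.frame(id = ids, gc = unname(x$gc), rank = rank,
             is_key_contributor = ids %in% x$key_contributors,
             row.names = NULL)
}

#' Proportion of relationship-structure variance in the leading components
#'
#' Sum of the k leading eigenvalues over the sum of all positive
#' eigenvalues (negative eigenvalues, which can arise from the IBD union
#' convention, are clamped to zero in the denominator). Accepts either a
#' [eigendecompose()] result, a [significant_components()] result (using
#' the spectrum its retention rule operated on), or a plain eigenvalue
#' vector.
#'
#' @param x eigenvalues: `grm_evd`, `parallel_analysis` or numeric vector.
#' @param k number of leading components (0 allowed).
#' @return fraction in [0, 1].
#' @export
proportion_variance <- function(x, k) {
  values <- if (inherits(x, "grm_evd")) x$values
            else if (inherits(x, "parallel_analysis")) x$observed
            else as.numeric(x)
  stop_if(k < 0 || k > length(values), "k out of range")
  if (k == 0) return(0)
  sum(values[seq_len(k)]) / sum(pmax(values, 0))
}

#' Identify key contributors in one call
#'
#' Chains [eigendecompose()], [significant_components()] and
#' [contribution_scores()] on a relationship matrix. The reported
#' proportion of variation comes from the spectrum the retention analysis
#' operated on (see [significant_components()]).
#'
#' @inheritParams significant_components
#' @return list of class `key_contributors_result`: `evd`,
#'   `parallel_analysis`, `contribution`, `proportion_variance`.
#' @export
key_contributors <- function(G, genotypes = NULL, alpha = 0.01,
                             iterations = 100,
                             null = c("paran", "marchenko", "permutation"),
                             rule = c("prefix", "count"), seed = NULL) {
  evd <- eigendecompose(G)
  pa <- significant_components(G, genotypes, alpha, iterations,
                               null = null, rule = rule, evd = evd,
                               seed = seed)
  stop_if(pa$k == 0, "no significant components")
  contrib <- contribution_scores(G, pa$k, evd = evd)
  structure(list(evd = evd, parallel_analysis = pa, contribution = contrib,
                 proportion_variance = proportion_variance(pa, pa$k)),
            class = "key_contributors_result")
}

#' @export
print.key_contributors_result <- function(x, ...) {
  cat("key_contributors_result: k =", x$parallel_analysis$k,
      "components capturing",
      sprintf("%.1f%%", 100 * x$proportion_variance),
      "of relationship variance\n")
  invisible(x)
}
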