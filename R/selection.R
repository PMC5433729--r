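selection_result <- function(strategy, selected, scores, n_requested) {
  structure(list(strategy = strategy, selected = selected,
                 scores = unname(scores), n_requested = n_requested),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection_result [", x$strategy, "]: ", length(x$selected),
      " individuals\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.selection_result <- function(x, ...) {
  data.frame(strategy = x$strategy, rank = seq_along(x$selected),
             id = x$selected, score = x$scores, row.names = NULL)
}

#' Select key contributors (Con strategy)
#'
#' Top-n individuals by genetic contribution score.
#'
#' @param contribution a [contribution_scores()] result.
#' @param n number of individuals to select.
#' @export
select_con <- function(contribution, n) {
  stopifnot(inherits(contribution, "contribution_result"))
  stop_if(n > length(contribution$gc), "n exceeds population size")
  ids <- contribution$ranking[seq_len(n)]
  selection_result("Con", ids, contribution$gc[as.character(ids)], n)
}

#' Greedy expected-relationship selection (Rel strategy)
#'
#' Forward selection maximizing the captured-relationship objective
#' v(S) = mean over the population of the diagonal of
#' G(.,S) G(S,S)^-1 G(S,.), the average variance of relationship profiles
#' explained by the selected set. A small ridge (1e-8 of the mean selected
#' diagonal) stabilizes the inverse, so duplicated individuals add zero
#' marginal value and are never picked twice.
#'
#' @param G symmetric relationship matrix.
#' @param n number of individuals to select.
#' @param candidates optional id subset eligible for selection.
#' @return a `selection_result`; scores are the objective after each pick.
#' @export
select_rel <- function(G, n, candidates = NULL) {
  ids <- matrix_ids(G)
  G <- check_symmetric(G)
  cand <- if (is.null(candidates)) seq_along(ids) else match(candidates, ids)
  stop_if(anyNA(cand), "unknown candidate id")
  stop_if(n > length(cand), "n exceeds candidate pool")
  sel <- integer(0)
  obj <- numeric(0)
  objective <- function(S) {
    B <- G[, S, drop = FALSE]
    K <- G[S, S, drop = FALSE]
    diag(K) <- diag(K) + 1e-8 * mean(diag(K))
    mean(rowSums((B %*% solve(K)) * B))
  }
  for (step in seq_len(n)) {
    pool <- setdiff(cand, sel)
    vals <- vapply(pool, function(c) objective(c(sel, c)), numeric(1))
    best <- pool[which.max(vals)]
    sel <- c(sel, best)
    obj <- c(obj, max(vals))
  }
  selection_result("Rel", ids[sel], obj, n)
}

#' Pedigree marginal-gene-contribution selection (Ped strategy)
#'
#' Iterative marginal-contribution (Boichard-style) ancestor analysis: the
#' expected gene contribution of every pedigree member to the reference set
#' follows the transmission recursion (each parent passes one half), with
#' genes flowing through already-selected ancestors blocked; each round
#' selects the individual with the largest remaining marginal contribution.
#'
#' @param pedigree pedigree data.frame.
#' @param reference_ids individuals whose gene pool is to be explained.
#' @param n number of ancestors to select.
#' @return a `selection_result`; scores are marginal contributions in
#'   [0, 1], whose sum never exceeds 1.
#' @export
select_ped <- function(pedigree, reference_ids, n) {
  ped <- validate_pedigree(pedigree)
  ord <- order(ped$generation)
  ped <- ped[ord, ]
  np <- nrow(ped)
  stop_if(!all(reference_ids %in% ped$id), "reference ids missing from pedigree")
  stop_if(n > np, "n exceeds pedigree size")
  ref <- match(reference_ids, ped$id)
  si <- ifelse(ped$sire == 0, 0L, match(ped$sire, ped$id))
  di <- ifelse(ped$dam == 0, 0L, match(ped$dam, ped$id))
  sel <- integer(0)
  scores <- numeric(0)
  for (round in seq_len(n)) {
    # C[j, a]: expected fraction of j's genome from a, paths through
    # selected ancestors removed
    C <- matrix(0, np, np)
    for (j in seq_len(np)) {
      if (j %in% sel) { C[j, j] <- 1; next }
      v <- numeric(np)
      if (si[j] > 0) v <- v + 0.5 * C[si[j], ]
      if (di[j] > 0) v <- v + 0.5 * C[di[j], ]
      v[sel] <- 0                      # genes already attributed
      v[j] <- 1
      C[j, ] <- v
    }
    q <- colMeans(C[ref, , drop = FALSE])
    q[sel] <- -Inf
    best <- which.max(q)
    sel <- c(sel, best)
    scores <- c(scores, q[best])
  }
  selection_result("Ped", ped$id[sel], scores, n)
}

#' Random selection (Ran strategy)
#'
#' Uniform sample without replacement, reproducible by seed.
#'
#' @param ids candidate identifiers.
#' @param n number to select.
#' @param seed optional RNG seed.
#' @export
select_random <- function(ids, n, seed = NULL) {
  stop_if(n > length(ids), "n exceeds candidate pool")
  sel <- with_seed(seed, sample(ids, n))
  selection_result("Ran", sel, rep(NA_real_, n), n)
}

#' Overlap between selection strategies
#'
#' Counts every exclusive intersection region among the selected sets
#' (the numbers a Venn diagram displays).
#'
#' @param selections named list of `selection_result` objects (or plain id
#'   vectors); at least two.
#' @return data.frame with one row per region: logical membership columns
#'   and `count`.
#' @export
overlap_report <- function(selections) {
  stop_if(length(selections) < 2, "need at least two selections")
  sets <- lapply(selections, function(s)
    if (inherits(s, "selection_result")) s$selected else s)
  nm <- names(sets) %||% paste0("set", seq_along(sets))
  if (is.null(names(sets)) || any(names(sets) == ""))
    names(sets) <- nm
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1,
                                                  dimnames = list(NULL, nm))
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))
  names(patterns) <- nm
  patterns <- patterns[rowSums(patterns) > 0, , drop = FALSE]
  patterns$count <- apply(patterns[, nm, drop = FALSE], 1, function(p)
    sum(apply(membership, 1, function(row) all(row == p))))
  rownames(patterns) <- NULL
  patterns
}
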