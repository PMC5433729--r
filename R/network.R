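#' Genetic distance matrix D = 1 - G
#'
#' Entrywise 1 - G. Negative distances (G > 1, possible for close relatives
#' under the IBD union convention or inbred diagonals) are clamped to zero;
#' the number of clamped off-diagonal entries is recorded in attribute
#' `n_clamped`.
#'
#' @param G symmetric relationship matrix.
#' @return distance matrix with attribute `n_clamped`.
#' @export
distance_matrix <- function(G) {
  G <- check_symmetric(G)
  D <- 1 - G
  off <- D < 0
  diag(off) <- FALSE
  n_clamped <- sum(off) / 2
  D[D < 0] <- 0
  attr(D, "n_clamped") <- n_clamped
  attr(D, "kind") <- "distance"
  D
}

#' k-nearest-neighbour population network
#'
#' For every individual the k smallest-distance neighbours are determined
#' (self excluded; ties at the k-th neighbour broken by input order). In
#' `"mutual"` mode an edge (i, j) is kept only when each is among the
#' other's k nearest neighbours; `"union"` keeps an edge when either is.
#' Edge weights are the genetic distances.
#'
#' @param D distance matrix (see [distance_matrix()]).
#' @param k neighbour count (default 10).
#' @param mode `"mutual"` (default) or `"union"`.
#' @return undirected `igraph` graph with vertex attribute `name` and edge
#'   attribute `distance`.
#' @export
knn_graph <- function(D, k = 10, mode = c("mutual", "union")) {
  mode <- match.arg(mode)
  n <- nrow(D)
  stop_if(k <= 0, "k must be positive")
  stop_if(k >= n, "k must be smaller than the number of individuals")
  ids <- matrix_ids(D)
  nn <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf
    nb <- order(d, ids)[seq_len(k)]     # ties broken by id order, so the
    nn[i, nb] <- TRUE                   # graph is permutation invariant
  }
  adj <- if (mode == "mutual") nn & t(nn) else nn | t(nn)
  adj[lower.tri(adj, diag = TRUE)] <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(ids))
  if (nrow(idx) > 0) {
    g <- igraph::add_edges(g, t(idx))
    g <- igraph::set_edge_attr(g, "distance", value = D[idx])
  }
  g <- igraph::set_graph_attr(g, "knn", k)
  g <- igraph::set_graph_attr(g, "mode", mode)
  g
}

#' Annotate network nodes with contribution scores and admixture
#'
#' Attaches per-individual genetic contribution scores (`gc`), a
#' key-contributor flag, and optional admixture proportions (one vertex
#' attribute `ancestry_<population>` per ancestry column; rows are
#' renormalized to sum to one with a warning when they deviate by more than
#' 1e-6).
#'
#' @param network igraph graph with vertex names.
#' @param gc named numeric vector of contribution scores covering all nodes.
#' @param admixture optional data.frame/matrix of ancestry proportions with
#'   individual ids as rownames (or an `id` column).
#' @param key_set ids flagged as key contributors.
#' @return the annotated graph.
#' @export
annotate_nodes <- function(network, gc, admixture = NULL, key_set = NULL) {
  ids <- igraph::V(network)$name
  stop_if(!all(ids %in% names(gc)), "gc does not cover all nodes")
  network <- igraph::set_vertex_attr(network, "gc", value = unname(gc[ids]))
  network <- igraph::set_vertex_attr(
    network, "key_contributor",
    value = ids %in% as.character(key_set %||% character(0)))
  if (!is.null(admixture)) {
    adm <- as.data.frame(admixture)
    if ("id" %in% names(adm)) {
      rownames(adm) <- as.character(adm$id)
      adm$id <- NULL
    }
    stop_if(!all(ids %in% rownames(adm)), "unknown node id in admixture table")
    adm <- adm[ids, , drop = FALSE]
    rs <- rowSums(adm)
    if (any(abs(rs - 1) > 1e-6)) {
      warning("admixture rows do not sum to 1; renormalizing")
    }
    adm <- adm / rs
    for (pop in colnames(adm))
      network <- igraph::set_vertex_attr(network, paste0("ancestry_", pop),
                                         value = adm[[pop]])
  }
  network
}

#' Export / import a population network
#'
#' GraphML preserves all node and edge attributes and round-trips through
#' standard graph tooling; the edge TSV lists `id1`, `id2`, `distance`.
#'
#' @param network igraph graph.
#' @param path output file.
#' @param format `"graphml"` or `"edge-tsv"`.
#' @export
export_graph <- function(network, path, format = c("graphml", "edge-tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(network)
    d <- igraph::E(network)$distance
    df <- data.frame(id1 = el[, 1], id2 = el[, 2],
                     distance = if (is.null(d)) NA_real_ else d)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname export_graph
#' @export
import_graph <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
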