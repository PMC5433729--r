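#' Parameters for IBD segment detection
#'
#' Defaults follow common practice for hash-based (Germline-style) detection
#' on 50k-density SNP data: 9-SNP slices, one tolerated homozygous-opposite
#' conflict when bridging a gap slice, and a 3 Mb minimum segment length.
#'
#' @param bits SNPs per hash slice (>= 2).
#' @param err_hom homozygous-opposite conflicts tolerated in a bridged slice.
#' @param min_length_bp minimum reported segment length in bp.
#' @export
ibd_params <- function(bits = 9, err_hom = 1, min_length_bp = 3e6) {
  stop_if(bits < 2, "bits must be >= 2")
  stop_if(err_hom < 0, "err_hom must be >= 0")
  stop_if(min_length_bp < 0, "min_length_bp must be >= 0")
  structure(list(bits = as.integer(bits), err_hom = as.integer(err_hom),
                 min_length_bp = as.numeric(min_length_bp)),
            class = "ibd_params")
}

#' Detect IBD segments between all pairs of individuals
#'
#' Seed-and-extend detection on phased haplotypes: per chromosome, SNPs are
#' partitioned into consecutive `bits`-SNP slices; haplotype pairs sharing
#' the identical allele word in a slice (found by exact hashing) match
#' there, maximal runs of consecutive matching slices form segments, and a
#' single interior gap slice is bridged when the two genotypes conflict at
#' no more than `err_hom` homozygous-opposite sites. Err-tolerant slices
#' join exact-match runs but never start or end one, so chance word
#' collisions do not seed spurious segments. Haplotype-level segments are
#' unioned per individual pair and per chromosome.
#'
#' Rows with `id1 == id2` report sharing between an individual's own two
#' haplotypes (the genomic-inbreeding component used for the matrix
#' diagonal).
#'
#' @param haps a `haplotype_set` with complete phased haplotypes.
#' @param params an [ibd_params()] object.
#' @return data.frame: `id1`, `id2`, `chrom`, `start`, `end`, `length_bp`,
#'   with `id1 <= id2` in input order.
#' @export
detect_ibd_segments <- function(haps, params = ibd_params()) {
  stopifnot(inherits(haps, "haplotype_set"))
  map <- validate_snp_map(haps$map)
  res <- .ibd_detect_cpp(haps$haps, as.integer(map$chrom), as.integer(map$pos),
                         params$bits, params$err_hom, params$min_length_bp,
                         TRUE)
  data.frame(id1 = haps$ids[res$i], id2 = haps$ids[res$j], chrom = res$chrom,
             start = res$start, end = res$end,
             length_bp = res$end - res$start + 1)
}

genome_length <- function(map) {
  lens <- attr(map, "chrom_length_bp")
  if (is.null(lens))
    lens <- tapply(map$pos, map$chrom, max)
  sum(as.numeric(lens))
}

#' IBD-proportion relationship matrix from a segment table
#'
#' Entry (i, j) is the summed segment length for the pair divided by the
#' total genome length; the diagonal is 1 plus the within-individual shared
#' proportion (self rows of the segment table).
#'
#' @param segments segment table from [detect_ibd_segments()].
#' @param ids ordered individual identifiers defining the matrix.
#' @param genome_length_bp total genome length used as denominator.
#' @return symmetric matrix with attribute `kind = "ibd"`.
#' @export
ibd_relationship_matrix <- function(segments, ids, genome_length_bp) {
  stop_if(genome_length_bp <= 0, "genome_length_bp must be positive")
  n <- length(ids)
  i <- match(segments$id1, ids)
  j <- match(segments$id2, ids)
  stop_if(anyNA(i) || anyNA(j), "segment references unknown id")
  G <- matrix(0, n, n)
  len <- as.numeric(segments$length_bp)
  for (r in seq_along(i)) {
    G[i[r], j[r]] <- G[i[r], j[r]] + len[r]
    if (i[r] != j[r]) G[j[r], i[r]] <- G[j[r], i[r]] + len[r]
  }
  G <- G / genome_length_bp
  diag(G) <- 1 + diag(G)
  dimnames(G) <- list(as.character(ids), as.character(ids))
  attr(G, "kind") <- "ibd"
  G
}

#' Genomic IBD relationship matrix from phased haplotypes
#'
#' One-step pipeline around [detect_ibd_segments()] that accumulates the
#' unioned shared length per pair directly (no per-segment table), suitable
#' for thousands of individuals.
#'
#' @inheritParams detect_ibd_segments
#' @param genome_length_bp denominator; defaults to the map's chromosome
#'   lengths (or the last marker position per chromosome).
#' @return symmetric IBD-proportion matrix, diagonal 1 + genomic inbreeding.
#' @export
ibd_grm <- function(haps, params = ibd_params(), genome_length_bp = NULL) {
  stopifnot(inherits(haps, "haplotype_set"))
  map <- validate_snp_map(haps$map)
  genome_length_bp <- genome_length_bp %||% genome_length(map)
  res <- .ibd_detect_cpp(haps$haps, as.integer(map$chrom), as.integer(map$pos),
                         params$bits, params$err_hom, params$min_length_bp,
                         FALSE)
  G <- res$shared_bp / genome_length_bp
  diag(G) <- 1 + diag(G)
  dimnames(G) <- list(as.character(haps$ids), as.character(haps$ids))
  attr(G, "kind") <- "ibd"
  G
}

#' Allele-sharing (VanRaden method 1) relationship matrix
#'
#' G = Z'Z / (2 * sum p (1 - p)) with Z the column-centered dosage matrix
#' (dosage - 2p) and p the sample allele frequency. Monomorphic SNPs are
#' excluded; missing dosages are centered to zero after frequency
#' estimation.
#'
#' @param dosages integer/numeric matrix, SNPs x individuals, values 0/1/2
#'   (NA allowed).
#' @return symmetric matrix with attribute `kind = "allele_sharing"`.
#' @export
allele_sharing_grm <- function(dosages) {
  stop_if(!is.matrix(dosages), "dosages must be a matrix (SNPs x individuals)")
  n_called <- rowSums(!is.na(dosages))
  stop_if(any(n_called == 0), "SNP with all dosages missing")
  p <- rowSums(dosages, na.rm = TRUE) / (2 * n_called)
  keep <- p > 0 & p < 1
  stop_if(!any(keep), "no polymorphic SNPs")
  Z <- dosages[keep, , drop = FALSE] - 2 * p[keep]
  Z[is.na(Z)] <- 0
  G <- crossprod(Z) / sum(2 * p[keep] * (1 - p[keep]))
  ids <- colnames(dosages) %||% as.character(seq_len(ncol(dosages)))
  dimnames(G) <- list(ids, ids)
  attr(G, "kind") <- "allele_sharing"
  G
}

#' Pedigree numerator relationship matrix (tabular method)
#'
#' Standard additive relationship matrix A: processing individuals in
#' generation order, A(i,j) = 0.5 (A(j,s) + A(j,d)) for j before i and
#' A(i,i) = 1 + 0.5 A(s,d), with unknown parents contributing zero.
#'
#' @param pedigree pedigree data.frame (`id`, `sire`, `dam`, `generation`;
#'   0 = unknown parent).
#' @return symmetric matrix with attribute `kind = "pedigree"`.
#' @export
pedigree_numerator_matrix <- function(pedigree) {
  ped <- validate_pedigree(pedigree)
  ord <- order(ped$generation)
  ped <- ped[ord, ]
  n <- nrow(ped)
  pos <- function(id) ifelse(id == 0, 0L, match(id, ped$id))
  si <- pos(ped$sire)
  di <- pos(ped$dam)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1) {
      j <- seq_len(i - 1L)
      v <- numeric(i - 1L)
      if (s > 0) v <- v + A[j, s]
      if (d > 0) v <- v + A[j, d]
      A[j, i] <- A[i, j] <- 0.5 * v
    }
    A[i, i] <- 1 + if (s > 0 && d > 0) 0.5 * A[s, d] else 0
  }
  dimnames(A) <- list(as.character(ped$id), as.character(ped$id))
  # restore the caller's individual order
  orig <- as.character(pedigree$id)
  A <- A[orig, orig]
  attr(A, "kind") <- "pedigree"
  A
}

#' Write / read a square relationship matrix as TSV
#'
#' Layout: header row of ids, first column of ids, tab-separated values.
#' The reader validates symmetry.
#'
#' @param G symmetric matrix with ids as dimnames.
#' @param path file path.
#' @export
write_relationship_matrix <- function(G, path) {
  ids <- matrix_ids(G)
  df <- data.frame(id = ids, G, check.names = FALSE)
  colnames(df) <- c("id", ids)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_relationship_matrix
#' @param kind relationship kind recorded on the returned matrix.
#' @export
read_relationship_matrix <- function(path, kind = "external") {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  ids <- as.character(df[[1]])
  G <- as.matrix(df[, -1, drop = FALSE])
  stop_if(ncol(G) != nrow(G), "matrix is not square")
  dimnames(G) <- list(ids, ids)
  G <- check_symmetric(G)
  attr(G, "kind") <- kind
  G
}
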