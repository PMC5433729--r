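#' SNP map with equally spaced markers
#'
#' Builds the marker map used throughout the package: `n_chrom` chromosomes,
#' each carrying `snps_per_chrom` equally spaced biallelic SNPs over
#' `chrom_length_mb` megabases. The default reproduces the simulated design
#' used for validation: 5 chromosomes x 100 Mb x 2,000 SNPs. Genetic length
#' is 1 Morgan per 100 Mb unless overridden.
#'
#' @param n_chrom number of chromosomes.
#' @param snps_per_chrom SNPs per chromosome.
#' @param chrom_length_mb physical chromosome length in megabases.
#' @param morgans_per_100mb genetic map density (Morgan per 100 Mb).
#' @return data.frame with columns `chrom`, `snp_id`, `pos` (1-based bp) and
#'   attributes `chrom_length_bp` and `chrom_morgans` (per-chromosome vectors).
#' @export
snp_map <- function(n_chrom = 5, snps_per_chrom = 2000, chrom_length_mb = 100,
                    morgans_per_100mb = 1) {
  stop_if(n_chrom < 1 || snps_per_chrom < 1, "empty map requested")
  len_bp <- round(chrom_length_mb * 1e6)
  spacing <- len_bp / snps_per_chrom
  pos <- as.integer(round(spacing * seq_len(snps_per_chrom)))
  map <- data.frame(
    chrom = rep(seq_len(n_chrom), each = snps_per_chrom),
    snp_id = sprintf("snp%d_%d", rep(seq_len(n_chrom), each = snps_per_chrom),
                     rep(seq_len(snps_per_chrom), n_chrom)),
    pos = rep(pos, n_chrom)
  )
  attr(map, "chrom_length_bp") <- rep(len_bp, n_chrom)
  attr(map, "chrom_morgans") <- rep(len_bp / 1e8 * morgans_per_100mb, n_chrom)
  map
}

validate_snp_map <- function(map) {
  stop_if(!all(c("chrom", "snp_id", "pos") %in% names(map)),
          "map needs columns chrom, snp_id, pos")
  ok <- tapply(map$pos, map$chrom, function(p) all(diff(p) > 0))
  stop_if(!all(unlist(ok)), "positions must be strictly increasing per chromosome")
  if (is.null(attr(map, "chrom_length_bp")))
    attr(map, "chrom_length_bp") <-
      tapply(map$pos, map$chrom, max)[as.character(unique(map$chrom))]
  if (is.null(attr(map, "chrom_morgans")))
    attr(map, "chrom_morgans") <- attr(map, "chrom_length_bp") / 1e8
  map
}

#' Simulate a non-overlapping-generation breeding pedigree
#'
#' Base population of `n_males` unrelated males and `n_females` unrelated
#' females. Each subsequent generation mates every male of the previous
#' generation with `n_females / n_males` distinct females; every dam produces
#' one female offspring, except `n_double_dams` dams (drawn uniformly at
#' random each generation) which produce one male and one female. With the
#' defaults each generation therefore contains exactly 20 males and 1,000
#' females, and five generations give 5,100 individuals.
#'
#' @param n_generations number of generations including the base (>= 1).
#' @param n_males,n_females males/females per generation; `n_males` must
#'   divide `n_females`.
#' @param n_double_dams dams per generation producing two offspring.
#' @param seed optional RNG seed.
#' @return data.frame with columns `id`, `sire`, `dam` (0 = unknown), `sex`
#'   ("M"/"F") and `generation` (0-based).
#' @export
simulate_pedigree <- function(n_generations = 5, n_males = 20,
                              n_females = 1000, n_double_dams = 20,
                              seed = NULL) {
  stop_if(n_generations < 1, "n_generations must be >= 1")
  stop_if(n_females %% n_males != 0, "n_males must divide n_females")
  stop_if(n_double_dams > n_females, "more double dams than dams")
  stop_if(n_double_dams != n_males,
          "closed design needs n_double_dams == n_males (male replacement)")
  with_seed(seed, {
    per_gen <- n_males + n_females
    id <- seq_len(per_gen)
    ped <- data.frame(id = id, sire = 0L, dam = 0L,
                      sex = rep(c("M", "F"), c(n_males, n_females)),
                      generation = 0L)
    males <- id[seq_len(n_males)]
    females <- id[-seq_len(n_males)]
    next_id <- per_gen + 1L
    dams_per_sire <- n_females %/% n_males
    for (g in seq_len(n_generations - 1L)) {
      assigned <- sample(females)                      # random mate allocation
      sire_of <- rep(males, each = dams_per_sire)
      double <- sample(assigned, n_double_dams)        # dams with two offspring
      n_off <- n_females + n_double_dams
      off_sex <- character(n_off)
      off_sire <- integer(n_off)
      off_dam <- integer(n_off)
      j <- 0L
      for (i in seq_along(assigned)) {
        dam <- assigned[i]
        kids <- if (dam %in% double) c("M", "F") else "F"
        for (s in kids) {
          j <- j + 1L
          off_sex[j] <- s
          off_sire[j] <- sire_of[i]
          off_dam[j] <- dam
        }
      }
      ord <- c(which(off_sex == "M"), which(off_sex == "F"))  # males first
      off <- data.frame(id = seq.int(next_id, length.out = n_off),
                        sire = off_sire[ord], dam = off_dam[ord],
                        sex = off_sex[ord], generation = g)
      ped <- rbind(ped, off)
      males <- off$id[off$sex == "M"]
      females <- off$id[off$sex == "F"]
      next_id <- next_id + n_off
    }
    ped
  })
}

validate_pedigree <- function(ped) {
  stop_if(!all(c("id", "sire", "dam", "sex", "generation") %in% names(ped)),
          "pedigree needs columns id, sire, dam, sex, generation")
  stop_if(anyDuplicated(ped$id) > 0, "duplicated pedigree ids")
  gen <- ped$generation[match(ped$id, ped$id)]
  for (p in c("sire", "dam")) {
    known <- ped[[p]] != 0
    idx <- match(ped[[p]][known], ped$id)
    stop_if(anyNA(idx), "unknown ", p, " id in pedigree")
    stop_if(any(ped$generation[idx] >= ped$generation[known]),
            p, " must belong to an earlier generation")
  }
  ped
}

#' Simulate founder haplotypes with independent alleles
#'
#' Allele frequencies are drawn per SNP from Uniform(`maf[1]`, `maf[2]`)
#' (or fixed when `maf` has length one); alleles are then sampled
#' independently for every founder haplotype, i.e. founders carry no linkage
#' disequilibrium and are mutually unrelated.
#'
#' @param map SNP map (see [snp_map()]).
#' @param n_founders number of founder individuals (2 haplotypes each).
#' @param maf length-2 range or single fixed allele frequency, in (0, 1).
#' @param ids founder individual identifiers.
#' @param seed optional RNG seed.
#' @return a `haplotype_set`: list with `haps` (raw matrix, SNPs x
#'   2*n_founders, columns paired paternal/maternal per individual), `map`,
#'   `ids` and per-SNP `freq`.
#' @export
simulate_founder_haplotypes <- function(map, n_founders = 1020,
                                        maf = c(0.05, 0.95),
                                        ids = seq_len(n_founders),
                                        seed = NULL) {
  map <- validate_snp_map(map)
  stop_if(length(maf) < 1 || length(maf) > 2, "maf must have length 1 or 2")
  stop_if(any(maf <= 0) || any(maf >= 1),
          "allele frequencies must lie strictly inside (0, 1)")
  stop_if(length(ids) != n_founders, "ids must match n_founders")
  m <- nrow(map)
  with_seed(seed, {
    freq <- if (length(maf) == 2) runif(m, min(maf), max(maf)) else rep(maf, m)
    H <- 2L * n_founders
    # prob recycles per column (column-major fill), aligning freq with SNPs
    haps <- matrix(as.raw(rbinom(m * H, 1L, freq)), m, H)
    haplotype_set(haps, map, ids, freq = freq)
  })
}

haplotype_set <- function(haps, map, ids, freq = NULL) {
  stop_if(ncol(haps) != 2L * length(ids), "need two haplotype columns per id")
  stop_if(nrow(haps) != nrow(map), "haplotype rows must match map")
  structure(list(haps = haps, map = map, ids = ids, freq = freq),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("haplotype_set:", length(x$ids), "individuals,", nrow(x$map), "SNPs on",
      length(unique(x$map$chrom)), "chromosome(s)\n")
  invisible(x)
}

n_ind <- function(hs) length(hs$ids)

#' Allele dosage matrix of a haplotype set
#'
#' @param hs a `haplotype_set`.
#' @return integer matrix (SNPs x individuals) of alternate-allele dosages
#'   0/1/2, with individual ids as column names.
#' @export
dosage_matrix <- function(hs) {
  H <- ncol(hs$haps)
  d <- matrix(as.integer(hs$haps[, seq(1, H, 2), drop = FALSE]), nrow(hs$haps)) +
       matrix(as.integer(hs$haps[, seq(2, H, 2), drop = FALSE]), nrow(hs$haps))
  colnames(d) <- as.character(hs$ids)
  rownames(d) <- hs$map$snp_id
  d
}

# One meiosis on one chromosome under the Haldane model: Poisson(morgans)
# crossovers, positions uniform, no interference. Returns half-open
# (start, end] segments with the parental haplotype (1 or 2) per segment.
meiosis_segments <- function(len_bp, morgans) {
  n_co <- rpois(1L, morgans)
  breaks <- if (n_co > 0) sort(runif(n_co, 0, len_bp)) else numeric(0)
  phase <- sample(1:2, 1L)
  k <- length(breaks) + 1L
  cbind(start = c(0, breaks), end = c(breaks, len_bp),
        hap = rep(c(phase, 3L - phase), length.out = k))
}

#' Gene dropping through a pedigree
#'
#' Transmits founder haplotypes through the pedigree with Haldane
#' recombination (Poisson crossovers at the map's genetic length, uniform
#' positions, no interference), optionally tracking for every haplotype the
#' mosaic of founder-haplotype segments it is composed of.
#'
#' @param pedigree pedigree data.frame (see [simulate_pedigree()]); every
#'   non-founder needs both parents present.
#' @param founder_haps `haplotype_set` covering all pedigree founders.
#' @param seed optional RNG seed.
#' @param track_ancestry record founder-segment mosaics (needed for
#'   [true_ibd_matrix()]).
#' @return list with `haplotypes` (a `haplotype_set` over all pedigree
#'   members, columns ordered like the pedigree) and `tracks` (an
#'   `ancestry_tracks` object or NULL).
#' @export
drop_genes <- function(pedigree, founder_haps, seed = NULL,
                       track_ancestry = TRUE) {
  ped <- validate_pedigree(pedigree)
  map <- founder_haps$map
  chroms <- unique(map$chrom)
  lens <- attr(map, "chrom_length_bp")
  morg <- attr(map, "chrom_morgans")
  chrom_rows <- lapply(chroms, function(cc) which(map$chrom == cc))
  chrom_pos <- lapply(chrom_rows, function(r) map$pos[r])

  founders <- ped$id[ped$sire == 0 & ped$dam == 0]
  stop_if(!all(founders %in% founder_haps$ids),
          "founder haplotypes missing for some pedigree founders")
  non_founders <- ped$id[ped$sire != 0 | ped$dam != 0]
  stop_if(any(ped$sire[match(non_founders, ped$id)] == 0) ||
          any(ped$dam[match(non_founders, ped$id)] == 0),
          "non-founders need both parents")

  n <- nrow(ped)
  m <- nrow(map)
  haps <- matrix(as.raw(0L), m, 2L * n)
  tracks <- if (track_ancestry) vector("list", 2L * n) else NULL

  idx_of <- function(ids) match(ids, ped$id)
  ord <- order(ped$generation)

  with_seed(seed, {
    for (r in ord) {
      i <- r
      cols <- c(2L * i - 1L, 2L * i)
      if (ped$sire[r] == 0) {               # founder: copy stored haplotypes
        fi <- match(ped$id[r], founder_haps$ids)
        src <- c(2L * fi - 1L, 2L * fi)
        haps[, cols] <- founder_haps$haps[, src]
        if (track_ancestry) {
          tracks[[cols[1]]] <- lapply(seq_along(chroms), function(ci)
            cbind(start = 0, end = lens[ci], founder = src[1]))
          tracks[[cols[2]]] <- lapply(seq_along(chroms), function(ci)
            cbind(start = 0, end = lens[ci], founder = src[2]))
        }
        next
      }
      for (side in 1:2) {                    # 1 = paternal, 2 = maternal
        par <- if (side == 1) ped$sire[r] else ped$dam[r]
        pi <- idx_of(par)
        pcols <- c(2L * pi - 1L, 2L * pi)
        child_col <- cols[side]
        child_tr <- if (track_ancestry) vector("list", length(chroms)) else NULL
        for (ci in seq_along(chroms)) {
          seg <- meiosis_segments(lens[ci], morg[ci])
          rows <- chrom_rows[[ci]]
          pos <- chrom_pos[[ci]]
          # SNP index ranges per segment: pos in (start, end]
          cut <- findInterval(seg[, "end"], pos)
          lo <- c(0L, head(cut, -1L)) + 1L
          for (s in seq_len(nrow(seg))) {
            if (lo[s] > cut[s]) next
            rr <- rows[lo[s]:cut[s]]
            haps[rr, child_col] <- haps[rr, pcols[seg[s, "hap"]]]
          }
          if (track_ancestry) {
            pieces <- vector("list", nrow(seg))
            for (s in seq_len(nrow(seg))) {
              pt <- tracks[[pcols[seg[s, "hap"]]]][[ci]]
              keep <- pt[, "end"] > seg[s, "start"] & pt[, "start"] < seg[s, "end"]
              if (!any(keep)) next
              sub <- pt[keep, , drop = FALSE]
              sub[, "start"] <- pmax(sub[, "start"], seg[s, "start"])
              sub[, "end"] <- pmin(sub[, "end"], seg[s, "end"])
              pieces[[s]] <- sub
            }
            tr <- do.call(rbind, pieces)
            # merge adjacent pieces inheriting the same founder haplotype
            if (nrow(tr) > 1) {
              new_grp <- c(TRUE,
                           !(tr[-nrow(tr), "founder"] == tr[-1, "founder"] &
                             abs(tr[-nrow(tr), "end"] - tr[-1, "start"]) < 1e-9))
              grp <- cumsum(new_grp)
              tr <- cbind(
                start = as.numeric(tapply(tr[, "start"], grp, function(z) z[1])),
                end = as.numeric(tapply(tr[, "end"], grp, function(z) z[length(z)])),
                founder = tr[new_grp, "founder"])
            }
            child_tr[[ci]] <- tr
          }
        }
        if (track_ancestry) tracks[[child_col]] <- child_tr
      }
    }
    out_haps <- haplotype_set(haps, map, ped$id)
    tr_obj <- if (track_ancestry)
      structure(list(tracks = tracks, ids = ped$id, map = map,
                     chrom_length_bp = lens),
                class = "ancestry_tracks") else NULL
    list(haplotypes = out_haps, tracks = tr_obj)
  })
}

#' @export
print.ancestry_tracks <- function(x, ...) {
  cat("ancestry_tracks:", length(x$ids), "individuals,",
      length(x$tracks[[1]]), "chromosome(s)\n")
  invisible(x)
}

#' Exact IBD-proportion matrix from ancestry tracks
#'
#' For a pair (i, j) the entry is the fraction of the genome at which any
#' haplotype of i carries the same founder-haplotype label as any haplotype
#' of j, each position counted once (union over the four haplotype
#' combinations). The diagonal is 1 + the fraction shared between an
#' individual's own two haplotypes (1 + genomic inbreeding), mirroring
#' numerator-relationship conventions.
#'
#' @param tracks `ancestry_tracks` from [drop_genes()].
#' @param ids individuals to include (default all).
#' @return symmetric relationship matrix with attribute `kind = "ibd"`.
#' @export
true_ibd_matrix <- function(tracks, ids = tracks$ids) {
  idx <- match(ids, tracks$ids)
  stop_if(anyNA(idx), "unknown ids")
  n <- length(idx)
  nchrom <- length(tracks$tracks[[2L * idx[1] - 1L]])
  total <- sum(tracks$chrom_length_bp)
  # per-haplotype per-chromosome end vectors and label vectors
  ends <- labs <- vector("list", 2L * n)
  for (a in seq_len(n)) {
    for (s in 1:2) {
      tr <- tracks$tracks[[2L * idx[a] - 2L + s]]
      ends[[2L * a - 2L + s]] <- lapply(tr, function(t) t[, "end"])
      labs[[2L * a - 2L + s]] <- lapply(tr, function(t) t[, "founder"])
    }
  }
  G <- matrix(0, n, n)
  lab_at <- function(h, ci, q) {
    e <- ends[[h]][[ci]]
    labs[[h]][[ci]][findInterval(q, e) + 1L]
  }
  for (a in seq_len(n)) {
    for (b in a:n) {
      shared <- 0
      for (ci in seq_len(nchrom)) {
        e <- sort(unique(c(ends[[2L * a - 1L]][[ci]], ends[[2L * a]][[ci]],
                           ends[[2L * b - 1L]][[ci]], ends[[2L * b]][[ci]])))
        w <- diff(c(0, e))
        mid <- e - w / 2
        l1 <- lab_at(2L * a - 1L, ci, mid); l2 <- lab_at(2L * a, ci, mid)
        l3 <- lab_at(2L * b - 1L, ci, mid); l4 <- lab_at(2L * b, ci, mid)
        hit <- if (a == b) l1 == l2 else
          (l1 == l3) | (l1 == l4) | (l2 == l3) | (l2 == l4)
        shared <- shared + sum(w[hit])
      }
      val <- shared / total
      if (a == b) G[a, a] <- 1 + val else G[a, b] <- G[b, a] <- val
    }
  }
  dimnames(G) <- list(as.character(ids), as.character(ids))
  attr(G, "kind") <- "ibd"
  G
}

#' Simulate the full breeding design
#'
#' Convenience wrapper chaining [simulate_pedigree()],
#' [simulate_founder_haplotypes()] and [drop_genes()] under a single seed
#' (split into named substreams). Defaults reproduce the validation design:
#' 5 generations of 20 males x 1,000 females and 5 chromosomes x 100 Mb x
#' 2,000 SNPs (5,100 individuals, 10,000 SNPs).
#'
#' @param n_generations generations including the base.
#' @param seed master RNG seed.
#' @param n_chrom,snps_per_chrom,chrom_length_mb map design.
#' @param n_males,n_females,n_double_dams pedigree design.
#' @param maf founder allele-frequency range.
#' @param track_ancestry keep founder mosaics (memory ~ O(individuals)).
#' @return list of class `simulated_population` with elements `pedigree`,
#'   `haplotypes`, `tracks`, `map`.
#' @export
simulate_population <- function(n_generations = 5, seed = NULL, n_chrom = 5,
                                snps_per_chrom = 2000, chrom_length_mb = 100,
                                n_males = 20, n_females = 1000,
                                n_double_dams = 20, maf = c(0.05, 0.95),
                                track_ancestry = TRUE) {
  seeds <- derive_seeds(seed, 3)
  map <- snp_map(n_chrom, snps_per_chrom, chrom_length_mb)
  ped <- simulate_pedigree(n_generations, n_males, n_females, n_double_dams,
                           seed = seeds[[1]])
  founders <- ped$id[ped$generation == 0]
  fh <- simulate_founder_haplotypes(map, length(founders), maf,
                                    ids = founders, seed = seeds[[2]])
  dropped <- drop_genes(ped, fh, seed = seeds[[3]],
                        track_ancestry = track_ancestry)
  structure(list(pedigree = ped, haplotypes = dropped$haplotypes,
                 tracks = dropped$tracks, map = map),
            class = "simulated_population")
}

#' @export
print.simulated_population <- function(x, ...) {
  cat("simulated_population:", nrow(x$pedigree), "individuals over",
      max(x$pedigree$generation) + 1, "generations;",
      nrow(x$map), "SNPs\n")
  invisible(x)
}
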