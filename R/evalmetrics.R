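#' Subset a haplotype set by individual
#'
#' @param hs a `haplotype_set`.
#' @param ids individuals to keep (order preserved as given).
#' @export
subset_haplotypes <- function(hs, ids) {
  idx <- match(ids, hs$ids)
  stop_if(anyNA(idx), "unknown ids")
  cols <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  haplotype_set(hs$haps[, cols, drop = FALSE], hs$map, hs$ids[idx],
                freq = hs$freq)
}

#' Haplotype switch error rate
#'
#' At every heterozygous site the inferred phase is oriented relative to the
#' true phase; a switch is an orientation change between consecutive
#' heterozygous sites. Switches are counted within chromosomes only, and
#' the per-individual rate divides the pooled switch count by
#' sum over chromosomes of (heterozygous sites - 1). A genome-wide swap of
#' the two haplotypes is not an error (orientation is relative), and
#' homozygous sites are transparent.
#'
#' @param truth,inferred `haplotype_set` objects over the same individuals
#'   and SNPs with identical genotypes (only phase may differ).
#' @return list of class `switch_error_report`: `per_individual`
#'   (id, het, switches, denom, rate), `mean_rate` (mean of defined
#'   per-individual rates) and `pooled_rate` (cohort-pooled counts).
#' @export
switch_error_rate <- function(truth, inferred) {
  stop_if(!identical(as.character(truth$ids), as.character(inferred$ids)),
          "individual sets differ")
  stop_if(nrow(truth$map) != nrow(inferred$map), "SNP sets differ")
  map <- truth$map
  chroms <- unique(map$chrom)
  n <- length(truth$ids)
  het <- sw <- den <- numeric(n)
  for (i in seq_len(n)) {
    c1 <- 2L * i - 1L
    t1 <- as.integer(truth$haps[, c1]); t2 <- as.integer(truth$haps[, c1 + 1L])
    f1 <- as.integer(inferred$haps[, c1]); f2 <- as.integer(inferred$haps[, c1 + 1L])
    stop_if(any(t1 + t2 != f1 + f2),
            "genotype mismatch between truth and inferred (not a phase difference)")
    for (cc in chroms) {
      r <- which(map$chrom == cc)
      h <- r[t1[r] + t2[r] == 1L]
      if (length(h) == 0) next
      orient <- t1[h] == f1[h]
      het[i] <- het[i] + length(h)
      den[i] <- den[i] + length(h) - 1L
      if (length(h) > 1) sw[i] <- sw[i] + sum(diff(orient) != 0)
    }
  }
  rate <- ifelse(den > 0, sw / den, NA_real_)
  per <- data.frame(id = truth$ids, het = het, switches = sw, denom = den,
                    rate = rate)
  structure(list(per_individual = per,
                 mean_rate = mean(rate, na.rm = TRUE),
                 pooled_rate = sum(sw) / max(sum(den), 1)),
            class = "switch_error_report")
}

#' @export
print.switch_error_report <- function(x, ...) {
  cat(sprintf("switch_error_report: mean rate %.4f (%d individuals)\n",
              x$mean_rate, nrow(x$per_individual)))
  invisible(x)
}

#' Randomly perturb haplotype phase
#'
#' Deliberately noisy re-phaser used for calibration: walking the
#' heterozygous sites of each chromosome, the phase orientation is flipped
#' with probability `rate` at every junction between consecutive
#' heterozygous sites, so the expected switch error rate equals `rate`.
#'
#' @param hs a `haplotype_set`.
#' @param rate per-junction orientation flip probability.
#' @param seed optional RNG seed.
#' @return a `haplotype_set` with identical genotypes and perturbed phase.
#' @export
flip_phase <- function(hs, rate, seed = NULL) {
  stop_if(rate < 0 || rate > 1, "rate must be in [0, 1]")
  map <- hs$map
  chroms <- unique(map$chrom)
  haps <- hs$haps
  with_seed(seed, {
    for (i in seq_along(hs$ids)) {
      c1 <- 2L * i - 1L
      a1 <- as.integer(haps[, c1]); a2 <- as.integer(haps[, c1 + 1L])
      for (cc in chroms) {
        r <- which(map$chrom == cc)
        h <- r[a1[r] + a2[r] == 1L]
        if (length(h) < 2) next
        flips <- rbinom(length(h) - 1L, 1L, rate)
        orient <- cumsum(c(0L, flips)) %% 2L
        swap <- h[orient == 1L]
        if (length(swap)) {
          tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
        }
      }
      haps[, c1] <- as.raw(a1); haps[, c1 + 1L] <- as.raw(a2)
    }
    haplotype_set(haps, map, hs$ids, freq = hs$freq)
  })
}

#' Naive reference-copy phaser
#'
#' A deliberately simple population phaser for comparing reference-set
#' selection strategies: each chromosome is cut into windows of
#' `window_snps` SNPs; within a window the reference haplotype with the
#' fewest conflicts against the target's homozygous genotypes guides the
#' phase of the heterozygous sites (the target's first haplotype copies the
#' guide allele). Windows are phased independently, so phase switches arise
#' wherever the panel lacks a haplotype closely related to the target --
#' reference sets rich in relatives of the target phase it well.
#'
#' @param targets `haplotype_set` of individuals to phase (their haplotypes
#'   supply the genotypes; the phase is re-inferred).
#' @param reference `haplotype_set` of phased reference individuals.
#' @param window_snps window width in SNPs.
#' @return a `haplotype_set` with inferred phase.
#' @export
phase_with_reference <- function(targets, reference, window_snps = 50) {
  stop_if(nrow(targets$map) != nrow(reference$map),
          "targets and reference must share the SNP map")
  map <- targets$map
  chroms <- unique(map$chrom)
  out <- targets$haps
  refH <- matrix(as.integer(reference$haps), nrow(reference$haps))
  for (i in seq_along(targets$ids)) {
    c1 <- 2L * i - 1L
    g <- as.integer(targets$haps[, c1]) + as.integer(targets$haps[, c1 + 1L])
    h1 <- integer(length(g)); h2 <- integer(length(g))
    for (cc in chroms) {
      r <- which(map$chrom == cc)
      starts <- seq(1L, length(r), by = window_snps)
      for (s in starts) {
        w <- r[s:min(s + window_snps - 1L, length(r))]
        gw <- g[w]
        R <- refH[w, , drop = FALSE]
        mism <- colSums((gw == 0L) & (R == 1L)) + colSums((gw == 2L) & (R == 0L))
        guide <- R[, which.min(mism)]
        hw1 <- gw %/% 2L                # homozygous sites
        hetw <- gw == 1L
        hw1[hetw] <- guide[hetw]
        h1[w] <- hw1
        h2[w] <- gw - hw1
      }
    }
    out[, c1] <- as.raw(h1)
    out[, c1 + 1L] <- as.raw(h2)
  }
  haplotype_set(out, map, targets$ids, freq = targets$freq)
}

#' Within-reference phasing accuracy of a selected set
#'
#' Evaluation harness for selection strategies: every member of the
#' selected reference set is re-phased from the remaining members with
#' [phase_with_reference()] and compared with its true phase. Cohorts whose
#' members are mutual relatives (e.g. key contributors spanning a sire
#' lineage) phase accurately; maximally unrelated panels do not.
#'
#' @param hs truth `haplotype_set` covering the population.
#' @param ids the selected reference set (>= 2 individuals).
#' @param window_snps window width passed to the phaser.
#' @return a `switch_error_report` over the selected set.
#' @export
reference_phasing_error <- function(hs, ids, window_snps = 50) {
  stop_if(length(ids) < 2, "need at least two reference individuals")
  sub <- subset_haplotypes(hs, ids)
  inferred <- sub
  for (i in seq_along(ids)) {
    target <- subset_haplotypes(sub, ids[i])
    panel <- subset_haplotypes(sub, ids[-i])
    ph <- phase_with_reference(target, panel, window_snps)
    inferred$haps[, c(2L * i - 1L, 2L * i)] <- ph$haps
  }
  switch_error_rate(sub, inferred)
}

#' Genome-based inbreeding coefficient
#'
#' Method-of-moments excess-homozygosity estimator per individual:
#' f = (observed hom count - expected hom count) / (m - expected hom count),
#' with the expectation sum(1 - 2 p q) taken over the individual's called,
#' polymorphic SNPs at sample allele frequencies.
#'
#' @param dosages matrix (SNPs x individuals) of dosages 0/1/2 (NA allowed).
#' @return data.frame `id`, `o_hom`, `e_hom`, `m`, `f`.
#' @export
inbreeding_coefficient <- function(dosages) {
  stop_if(!is.matrix(dosages), "dosages must be a matrix")
  n_called <- rowSums(!is.na(dosages))
  p <- rowSums(dosages, na.rm = TRUE) / (2 * pmax(n_called, 1))
  keep <- p > 0 & p < 1 & n_called > 0
  stop_if(!any(keep), "no polymorphic SNPs")
  d <- dosages[keep, , drop = FALSE]
  pq2 <- 2 * p[keep] * (1 - p[keep])
  called <- !is.na(d)
  o_hom <- colSums((d == 0 | d == 2) & called, na.rm = TRUE)
  e_hom <- colSums(called * (1 - pq2))
  m <- colSums(called)
  denom <- m - e_hom
  stop_if(any(denom <= 0), "degenerate expectation: m equals expected hom count")
  ids <- colnames(dosages) %||% as.character(seq_len(ncol(dosages)))
  data.frame(id = ids, o_hom = o_hom, e_hom = e_hom, m = m,
             f = (o_hom - e_hom) / denom, row.names = NULL)
}
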