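#' Genotype container
#'
#' Light container for unphased dosage data: `dosages` (SNPs x individuals,
#' 0/1/2/NA), `map` (see [snp_map()]) and `ids`.
#'
#' @param dosages dosage matrix.
#' @param map SNP map data.frame.
#' @param ids individual identifiers.
#' @export
genotype_set <- function(dosages, map, ids) {
  stop_if(nrow(dosages) != nrow(map), "dosage rows must match map")
  stop_if(ncol(dosages) != length(ids), "dosage columns must match ids")
  structure(list(dosages = dosages, map = map, ids = ids),
            class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat("genotype_set:", length(x$ids), "individuals,", nrow(x$map), "SNPs\n")
  invisible(x)
}

as_genotype_set <- function(x) {
  if (inherits(x, "genotype_set")) return(x)
  if (inherits(x, "haplotype_set"))
    return(genotype_set(dosage_matrix(x), x$map, x$ids))
  stop("cannot convert to genotype_set")
}

# ---- PLINK text (ped/map) ----------------------------------------------

#' Write / read PLINK text files (.ped/.map)
#'
#' Alleles are coded 1/2 (reference/alternate); missing genotypes are
#' "0 0". A `haplotype_set` writes its phased alleles in haplotype order
#' (the ped format itself is unphased). The reader counts allele "2"
#' dosages.
#'
#' @param x `haplotype_set` or `genotype_set`.
#' @param prefix file prefix (writes `prefix.ped` and `prefix.map`).
#' @param pedigree optional pedigree supplying sire/dam/sex columns.
#' @export
write_plink <- function(x, prefix, pedigree = NULL) {
  map <- if (inherits(x, "haplotype_set") || inherits(x, "genotype_set"))
    x$map else stop("unsupported input")
  write.table(data.frame(map$chrom, map$snp_id, 0L, as.integer(map$pos)),
              paste0(prefix, ".map"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  ids <- x$ids
  fam <- plink_fam_fields(ids, pedigree)
  if (inherits(x, "haplotype_set")) {
    H <- matrix(as.integer(x$haps), nrow(x$haps)) + 1L   # 1/2 coding
    al <- matrix(0L, length(ids), 2L * nrow(map))
    al[, seq(1, ncol(al), 2)] <- t(H[, seq(1, ncol(H), 2), drop = FALSE])
    al[, seq(2, ncol(al), 2)] <- t(H[, seq(2, ncol(H), 2), drop = FALSE])
  } else {
    d <- t(x$dosages)
    a1 <- ifelse(is.na(d), 0L, ifelse(d >= 1, 2L, 1L))
    a2 <- ifelse(is.na(d), 0L, ifelse(d == 2, 2L, 1L))
    al <- matrix(0L, length(ids), 2L * nrow(map))
    al[, seq(1, ncol(al), 2)] <- a1
    al[, seq(2, ncol(al), 2)] <- a2
  }
  write.table(cbind(fam, al), paste0(prefix, ".ped"), sep = " ",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

plink_fam_fields <- function(ids, pedigree = NULL) {
  if (is.null(pedigree)) {
    data.frame(fid = 1L, iid = as.character(ids), pat = 0L, mat = 0L,
               sex = 0L, pheno = -9L)
  } else {
    i <- match(ids, pedigree$id)
    stop_if(anyNA(i), "pedigree does not cover all ids")
    data.frame(fid = 1L, iid = as.character(ids),
               pat = pedigree$sire[i], mat = pedigree$dam[i],
               sex = ifelse(pedigree$sex[i] == "M", 1L, 2L), pheno = -9L)
  }
}

#' @rdname write_plink
#' @export
read_plink <- function(prefix) {
  map <- read.table(paste0(prefix, ".map"), sep = "\t",
                    col.names = c("chrom", "snp_id", "cm", "pos"),
                    colClasses = c("integer", "character", "numeric",
                                   "integer"))
  ped <- read.table(paste0(prefix, ".ped"), colClasses = "character")
  m <- nrow(map)
  stop_if(ncol(ped) != 6 + 2 * m, "ped/map column mismatch")
  ids <- ped[[2]]
  a1 <- t(as.matrix(ped[, 6 + seq(1, 2 * m, 2), drop = FALSE]))
  a2 <- t(as.matrix(ped[, 6 + seq(2, 2 * m, 2), drop = FALSE]))
  d <- (a1 == "2") + (a2 == "2")
  d[a1 == "0" | a2 == "0"] <- NA
  d <- matrix(as.integer(d), m, length(ids))
  colnames(d) <- ids
  map2 <- data.frame(chrom = map$chrom, snp_id = map$snp_id, pos = map$pos)
  genotype_set(d, validate_snp_map(map2), ids)
}

# ---- PLINK binary (bed/bim/fam) ----------------------------------------

#' Write / read PLINK binary files (.bed/.bim/.fam)
#'
#' SNP-major bed v1.00 (magic bytes 0x6c, 0x1b, 0x01); two-bit codes
#' 00 = hom A1, 01 = missing, 10 = het, 11 = hom A2, first sample in the
#' lowest bits. Round-trips the dosage matrix losslessly.
#'
#' @inheritParams write_plink
#' @export
write_plink_bed <- function(x, prefix, pedigree = NULL) {
  g <- as_genotype_set(x)
  map <- g$map
  write.table(data.frame(map$chrom, map$snp_id, 0L, as.integer(map$pos),
                         "A", "B"),
              paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(plink_fam_fields(g$ids, pedigree), paste0(prefix, ".fam"),
              sep = " ", quote = FALSE, row.names = FALSE, col.names = FALSE)
  n <- length(g$ids)
  m <- nrow(map)
  codes <- matrix(0L, 4L * ceiling(n / 4), m)
  codes[seq_len(n), ] <- c(0L, 2L, 3L)[t(g$dosages) + 1L]
  codes[is.na(codes)] <- 1L                              # missing genotype
  k <- nrow(codes) / 4
  dim(codes) <- c(4L, k * m)
  bytes <- as.raw(codes[1, ] + 4L * codes[2, ] + 16L * codes[3, ] +
                  64L * codes[4, ])
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(bytes, con)
  invisible(prefix)
}

#' @rdname write_plink_bed
#' @export
read_plink_bed <- function(prefix) {
  bim <- read.table(paste0(prefix, ".bim"), sep = "\t",
                    col.names = c("chrom", "snp_id", "cm", "pos", "a1", "a2"),
                    colClasses = c("integer", "character", "numeric",
                                   "integer", "character", "character"))
  fam <- read.table(paste0(prefix, ".fam"),
                    col.names = c("fid", "iid", "pat", "mat", "sex", "pheno"),
                    colClasses = "character")
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3 + ceiling(n / 4) * m)
  stop_if(!identical(raw[1:3], as.raw(c(0x6c, 0x1b, 0x01))),
          "not a SNP-major PLINK bed file (magic mismatch)")
  body <- as.integer(raw[-(1:3)])
  stop_if(length(body) != ceiling(n / 4) * m, "truncated bed file")
  codes <- rbind(body %% 4L, (body %/% 4L) %% 4L,
                 (body %/% 16L) %% 4L, (body %/% 64L) %% 4L)
  dim(codes) <- NULL
  codes <- matrix(codes, ncol = m)[seq_len(n), , drop = FALSE]
  d <- c(0L, NA_integer_, 1L, 2L)[codes + 1L]
  d <- matrix(d, ncol = m)
  d <- t(d)
  colnames(d) <- fam$iid
  map <- data.frame(chrom = bim$chrom, snp_id = bim$snp_id, pos = bim$pos)
  genotype_set(d, validate_snp_map(map), fam$iid)
}

# ---- VCF ----------------------------------------------------------------

#' Write phased haplotypes as VCF
#'
#' Minimal VCF 4.2 with phased GT fields ("0|1"); REF = A, ALT = B.
#'
#' @param hs a `haplotype_set`.
#' @param path output path (plain text).
#' @export
write_vcf <- function(hs, path) {
  map <- hs$map
  H <- matrix(as.integer(hs$haps), nrow(hs$haps))
  gt <- matrix(paste0(H[, seq(1, ncol(H), 2), drop = FALSE], "|",
                      H[, seq(2, ncol(H), 2), drop = FALSE]),
               nrow(map))
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", as.character(hs$ids)),
                    collapse = "\t"))
  fixed <- paste(map$chrom, map$pos, map$snp_id, "A", "B", ".", ".", ".",
                 "GT", sep = "\t")
  body <- paste(fixed, apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read phased haplotypes from VCF
#'
#' Requires the `vcfR` package. Only the GT field is used; all genotypes
#' must be phased ("|") and biallelic.
#'
#' @param path VCF path.
#' @return a `haplotype_set`.
#' @export
read_vcf_haps <- function(path) {
  stop_if(!requireNamespace("vcfR", quietly = TRUE),
          "read_vcf_haps needs the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  stop_if(any(!grepl("|", gt, fixed = TRUE)), "unphased genotypes in VCF")
  m <- nrow(gt)
  ids <- colnames(gt)
  h1 <- matrix(as.integer(substr(gt, 1, 1)), m)
  h2 <- matrix(as.integer(substr(gt, 3, 3)), m)
  haps <- matrix(as.raw(0), m, 2L * length(ids))
  haps[, seq(1, ncol(haps), 2)] <- as.raw(h1)
  haps[, seq(2, ncol(haps), 2)] <- as.raw(h2)
  map <- data.frame(chrom = as.integer(v@fix[, "CHROM"]),
                    snp_id = v@fix[, "ID"],
                    pos = as.integer(v@fix[, "POS"]))
  haplotype_set(haps, validate_snp_map(map), ids)
}

# ---- pedigree TSV -------------------------------------------------------

#' Write / read a pedigree table
#'
#' Tab-separated columns id, sire, dam, sex, generation; 0 marks an unknown
#' parent.
#'
#' @param pedigree pedigree data.frame.
#' @param path file path.
#' @export
write_pedigree <- function(pedigree, path) {
  write.table(pedigree[, c("id", "sire", "dam", "sex", "generation")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  ped <- read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("integer", "integer", "integer",
                                   "character", "integer"))
  validate_pedigree(ped)
}

# ---- quality control ----------------------------------------------------

#' Quality-control parameters
#'
#' @param min_maf minimum minor allele frequency (SNPs below are removed).
#' @param min_call_rate minimum genotype call rate per SNP.
#' @param hwe_p Hardy-Weinberg exact-test p-value threshold; `NULL`
#'   disables the filter (it is conventionally enabled for outbred
#'   populations and disabled for designed crosses).
#' @param mendel_check remove SNPs with parent-offspring conflicts
#'   (requires a pedigree in [qc_filter()]).
#' @param max_mendel_errors conflicts tolerated per SNP before removal.
#' @export
qc_params <- function(min_maf = 0.05, min_call_rate = 0.90, hwe_p = NULL,
                      mendel_check = FALSE, max_mendel_errors = 0) {
  stop_if(min_maf < 0 || min_maf > 1 || min_call_rate < 0 || min_call_rate > 1,
          "thresholds must lie in [0, 1]")
  structure(list(min_maf = min_maf, min_call_rate = min_call_rate,
                 hwe_p = hwe_p, mendel_check = mendel_check,
                 max_mendel_errors = max_mendel_errors),
            class = "qc_params")
}

# Hardy-Weinberg exact test (standard mid-less exact enumeration of
# heterozygote counts given allele counts).
hwe_exact_p <- function(n_het, n_hom1, n_hom2) {
  n <- n_het + n_hom1 + n_hom2
  if (n == 0) return(1)
  rare <- 2 * min(n_hom1, n_hom2) + n_het
  probs <- numeric(rare + 1)
  mid <- rare * (2 * n - rare) / (2 * n)
  mid <- floor(mid)
  if (mid %% 2 != rare %% 2) mid <- mid + 1
  probs[mid + 1] <- 1
  het <- mid
  while (het > 1) {
    hr <- (rare - het) / 2
    hc <- (2 * n - rare - het) / 2
    probs[het - 1] <- probs[het + 1] * het * (het - 1) /
      (4 * (hr + 1) * (hc + 1))
    het <- het - 2
  }
  het <- mid
  while (het <= rare - 2) {
    hr <- (rare - het) / 2
    hc <- (2 * n - rare - het) / 2
    probs[het + 3] <- probs[het + 1] * 4 * hr * hc /
      ((het + 2) * (het + 1))
    het <- het + 2
  }
  probs <- probs / sum(probs)
  sum(probs[probs <= probs[n_het + 1] + 1e-12])
}

#' Apply SNP quality-control filters
#'
#' Removes SNPs failing minor-allele-frequency, call-rate, Hardy-Weinberg
#' (exact test) or Mendelian-consistency screens and logs per-filter
#' removal counts. A SNP failing several filters is attributed to the first
#' in the order MAF, call rate, HWE, Mendel.
#'
#' @param x `genotype_set` (or `haplotype_set`).
#' @param params a [qc_params()] object.
#' @param pedigree pedigree used for the Mendelian screen.
#' @return list with `genotypes` (filtered `genotype_set`) and `log`
#'   (data.frame filter/removed).
#' @export
qc_filter <- function(x, params = qc_params(), pedigree = NULL) {
  g <- as_genotype_set(x)
  d <- g$dosages
  n <- ncol(d)
  called <- !is.na(d)
  call_rate <- rowMeans(called)
  p <- rowSums(d, na.rm = TRUE) / (2 * pmax(rowSums(called), 1))
  maf <- pmin(p, 1 - p)
  fail_maf <- maf < params$min_maf
  fail_cr <- !fail_maf & call_rate < params$min_call_rate
  fail_hwe <- rep(FALSE, nrow(d))
  if (!is.null(params$hwe_p)) {
    idx <- which(!fail_maf & !fail_cr)
    for (r in idx) {
      dr <- d[r, called[r, ]]
      pv <- hwe_exact_p(sum(dr == 1), sum(dr == 0), sum(dr == 2))
      fail_hwe[r] <- pv < params$hwe_p
    }
  }
  fail_mendel <- rep(FALSE, nrow(d))
  if (params$mendel_check) {
    stop_if(is.null(pedigree), "mendel_check needs a pedigree")
    errs <- mendel_error_counts(g, pedigree)
    fail_mendel <- !fail_maf & !fail_cr & !fail_hwe &
      errs > params$max_mendel_errors
  }
  drop <- fail_maf | fail_cr | fail_hwe | fail_mendel
  stop_if(all(drop), "all SNPs removed by QC")
  log <- data.frame(filter = c("maf", "call_rate", "hwe", "mendel"),
                    removed = c(sum(fail_maf), sum(fail_cr), sum(fail_hwe),
                                sum(fail_mendel)))
  map <- g$map[!drop, , drop = FALSE]
  attr(map, "chrom_length_bp") <- attr(g$map, "chrom_length_bp")
  attr(map, "chrom_morgans") <- attr(g$map, "chrom_morgans")
  list(genotypes = genotype_set(d[!drop, , drop = FALSE], map, g$ids),
       log = log)
}

# per-SNP count of parent-offspring opposite-homozygote conflicts
mendel_error_counts <- function(g, pedigree) {
  d <- g$dosages
  errs <- integer(nrow(d))
  idx <- match(g$ids, pedigree$id)
  for (i in which(!is.na(idx))) {
    for (par in c(pedigree$sire[idx[i]], pedigree$dam[idx[i]])) {
      if (par == 0) next
      pj <- match(as.character(par), as.character(g$ids))
      if (is.na(pj)) next
      conflict <- (d[, i] == 0 & d[, pj] == 2) | (d[, i] == 2 & d[, pj] == 0)
      errs <- errs + ifelse(is.na(conflict), 0L, conflict)
    }
  }
  errs
}

# ---- pipeline -----------------------------------------------------------

#' Run the three-step population-structure pipeline
#'
#' Step 1 builds the relationship matrix, step 2 identifies key
#' contributors (parallel analysis + contribution scores), step 3 builds
#' the annotated k-NN population network; optional selection strategies are
#' evaluated on the way. All outputs carry the seed and a parameter
#' fingerprint in comment headers, so reruns with the same configuration
#' are byte-identical.
#'
#' @param config named list (or path to a YAML file, requires the `yaml`
#'   package). Recognized blocks: `input` (either `sim:` with
#'   [simulate_population()] arguments or `plink:`/`grm:` file prefixes),
#'   `grm` (`method` = "ibd"/"vanraden"/"pedigree", plus [ibd_params()]
#'   fields), `keycontrib` (`alpha`, `iterations`, `null`, `seed`),
#'   `network` (`knn`, `mode`), `admixture` (TSV path), `select`
#'   (`strategies`, `n`, `seed`), `out_dir`.
#' @return invisible list with the computed objects and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    stop_if(!requireNamespace("yaml", quietly = TRUE),
            "reading a config file needs the yaml package")
    config <- yaml::read_yaml(config)
  }
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- provenance_header(config)

  # -- inputs
  sim <- NULL
  haps <- NULL
  ped <- NULL
  if (!is.null(config$input$sim)) {
    sim <- do.call(simulate_population, config$input$sim)
    haps <- sim$haplotypes
    ped <- sim$pedigree
  } else if (!is.null(config$input$plink)) {
    gset <- read_plink(config$input$plink)
  } else if (is.null(config$input$grm)) {
    stop("config$input must name sim, plink or grm")
  }

  # -- step 1: relationship matrix
  method <- config$grm$method %||% "ibd"
  if (!is.null(config$input$grm)) {
    G <- read_relationship_matrix(config$input$grm)
  } else if (method == "ibd") {
    stop_if(is.null(haps), "ibd method needs phased haplotypes (sim input)")
    G <- ibd_grm(haps, ibd_params(config$grm$bits %||% 9,
                                  config$grm$err_hom %||% 1,
                                  (config$grm$min_mb %||% 3) * 1e6))
  } else if (method == "vanraden") {
    d <- if (!is.null(haps)) dosage_matrix(haps) else gset$dosages
    G <- allele_sharing_grm(d)
  } else if (method == "pedigree") {
    stop_if(is.null(ped), "pedigree method needs a pedigree")
    G <- pedigree_numerator_matrix(ped)
  } else stop("unknown grm method: ", method)

  # -- step 2: key contributors
  kc_cfg <- config$keycontrib %||% list()
  genos <- if (!is.null(haps)) dosage_matrix(haps)
           else if (exists("gset", inherits = FALSE)) gset$dosages else NULL
  kc <- key_contributors(G, genotypes = genos,
                         alpha = kc_cfg$alpha %||% 0.01,
                         iterations = kc_cfg$iterations %||% 100,
                         null = kc_cfg$null %||% "paran",
                         seed = kc_cfg$seed %||% 1L)
  scores_path <- file.path(out_dir, "scores.tsv")
  write_tsv_with_header(as.data.frame(kc$contribution), scores_path, stamp)
  scree_path <- file.path(out_dir, "scree.tsv")
  write_tsv_with_header(
    data.frame(component = seq_along(kc$evd$values),
               eigenvalue = kc$evd$values,
               null_quantile = kc$parallel_analysis$null_quantiles),
    scree_path, stamp)

  # -- step 3: network
  net_cfg <- config$network %||% list()
  D <- distance_matrix(G)
  net <- knn_graph(D, k = net_cfg$knn %||% 10,
                   mode = net_cfg$mode %||% "mutual")
  adm <- if (!is.null(config$admixture))
    read.table(config$admixture, sep = "\t", header = TRUE) else NULL
  net <- annotate_nodes(net, kc$contribution$gc, adm,
                        key_set = kc$contribution$key_contributors)
  net_path <- file.path(out_dir, "net.graphml")
  export_graph(net, net_path)

  # -- optional selection comparison
  selections <- list()
  if (!is.null(config$select)) {
    n_sel <- config$select$n %||% kc$parallel_analysis$k
    for (s in config$select$strategies %||% "con") {
      selections[[s]] <- switch(
        s,
        con = select_con(kc$contribution, n_sel),
        rel = select_rel(G, n_sel),
        ped = { stop_if(is.null(ped), "ped strategy needs a pedigree")
                select_ped(ped, matrix_ids(G), n_sel) },
        ran = select_random(matrix_ids(G), n_sel,
                            seed = config$select$seed %||% 1L),
        stop("unknown strategy: ", s))
      write_tsv_with_header(as.data.frame(selections[[s]]),
                            file.path(out_dir, paste0("selection_", s, ".tsv")),
                            stamp)
    }
  }
  invisible(list(G = G, key_contributors = kc, network = net,
                 selections = selections,
                 paths = list(scores = scores_path, scree = scree_path,
                              network = net_path)))
}

provenance_header <- function(config) {
  cfg <- config[setdiff(names(config), "out_dir")]   # paths are not params
  fp <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  c(paste0("# keycontrib pipeline"),
    paste0("# seed: ", config$keycontrib$seed %||% "NA"),
    paste0("# params_fingerprint: ",
           format(sum(utf8ToInt(fp) * seq_along(utf8ToInt(fp))) %% 1e9,
                  scientific = FALSE)))
}

write_tsv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
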