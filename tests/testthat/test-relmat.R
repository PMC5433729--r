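test_that("identical haplotypes yield one segment spanning the chromosome", {
  map <- snp_map(1, 90, 0.09)            # 90 SNPs, tiny chromosome
  fh <- simulate_founder_haplotypes(map, n_founders = 3, seed = 2)
  # make individual 2 a copy of individual 1
  fh$haps[, 3:4] <- fh$haps[, 1:2]
  segs <- detect_ibd_segments(fh, ibd_params(bits = 9, min_length_bp = 0))
  pair <- segs[segs$id1 == 1 & segs$id2 == 2, ]
  expect_equal(nrow(pair), 1)
  expect_equal(pair$start, map$pos[1])
  expect_equal(pair$end, map$pos[90])
})

test_that("unrelated founders produce essentially no long segments", {
  map <- snp_map(1, 2000, 100)
  fh <- simulate_founder_haplotypes(map, n_founders = 60, maf = 0.5, seed = 4)
  segs <- detect_ibd_segments(fh, ibd_params(min_length_bp = 5e6))
  segs <- segs[segs$id1 != segs$id2, ]
  # 1,770 founder pairs: chance seed runs of >= 5 Mb are vanishingly rare
  expect_lte(nrow(segs), 1)
})

test_that("parent-offspring detected sharing covers most of the genome", {
  pop <- small_pop()
  ped <- pop$pedigree
  G <- ibd_grm(pop$haplotypes)
  kids <- ped[ped$generation == 1, ][1:20, ]
  po <- mapply(function(k, s) G[as.character(k), as.character(s)],
               kids$id, kids$sire)
  expect_true(all(po >= 0.5))
})

test_that("detected IBD matrix tracks the exact ancestry oracle", {
  pop <- small_pop()
  G <- ibd_grm(pop$haplotypes)
  Gt <- true_ibd_matrix(pop$tracks)
  ut <- upper.tri(G)
  expect_gt(cor(G[ut], Gt[ut]), 0.9)
  # detection loses slice boundaries and can overshoot a segment end only
  # by chance word matches in adjacent slices; allow a few slices of slack
  # for the hard bound and require near-universal compliance at two slices
  spacing <- diff(pop$map$pos[1:2])
  slice_frac <- 9 * spacing / keycontrib:::genome_length(pop$map)
  expect_lt(mean(G[ut] > Gt[ut] + 4 * slice_frac + 0.02), 0.01)
  expect_true(all(G[ut] <= Gt[ut] + 10 * slice_frac + 0.02))
  expect_equal(max(abs(G - t(G))), 0)
  expect_true(all(G[ut] >= 0 & G[ut] <= 1))
})

test_that("segment table and matrix accumulation agree", {
  pop <- small_pop()
  segs <- detect_ibd_segments(pop$haplotypes)
  G1 <- ibd_relationship_matrix(segs, pop$pedigree$id,
                                keycontrib:::genome_length(pop$map))
  G2 <- ibd_grm(pop$haplotypes)
  expect_equal(unclass(G1), unclass(G2), ignore_attr = TRUE)
})

test_that("ibd_relationship_matrix handles trivial inputs", {
  empty <- data.frame(id1 = integer(0), id2 = integer(0), chrom = integer(0),
                      start = integer(0), end = integer(0),
                      length_bp = integer(0))
  G <- ibd_relationship_matrix(empty, ids = 1:3, genome_length_bp = 100)
  expect_equal(unclass(G), diag(3), ignore_attr = TRUE)
  one <- data.frame(id1 = 1, id2 = 2, chrom = 1, start = 1, end = 250e6,
                    length_bp = 250e6)
  G <- ibd_relationship_matrix(one, ids = 1:2, genome_length_bp = 500e6)
  expect_equal(G[1, 2], 0.5)
  bad <- data.frame(id1 = 9, id2 = 2, chrom = 1, start = 1, end = 2,
                    length_bp = 2)
  expect_error(ibd_relationship_matrix(bad, ids = 1:2, 100), "unknown id")
})

test_that("VanRaden allele-sharing matrix follows the defining formula", {
  # n = 2, one SNP, dosages (0, 2): p = 0.5, Z = (-1, 1),
  # G = ZZ' / (2 p q) = [[2, -2], [-2, 2]]  (hand computation)
  expect_equal(unclass(allele_sharing_grm(matrix(c(0L, 2L), 1, 2))),
               matrix(c(2, -2, -2, 2), 2), ignore_attr = TRUE)
  # duplicated individual: identical rows/columns
  pop <- small_pop()
  dos <- dosage_matrix(pop$haplotypes)
  dos2 <- cbind(dos, dup = dos[, 5])
  G2 <- allele_sharing_grm(dos2)
  n <- ncol(dos2)
  expect_equal(G2[, 5], G2[, n], ignore_attr = TRUE)
  # centering property: row sums ~ 0 with sample frequencies
  expect_lt(max(abs(rowSums(G2))), 1e-8)
})

test_that("VanRaden diagonal averages one for a large unrelated panel", {
  map <- snp_map(2, 1000, 50)
  fh <- simulate_founder_haplotypes(map, n_founders = 300, seed = 10)
  G <- allele_sharing_grm(dosage_matrix(fh))
  expect_lt(abs(mean(diag(G)) - 1), 0.02)
})

test_that("pedigree numerator matrix reproduces textbook values", {
  # parent-offspring and full-sib-mating inbreeding
  ped <- data.frame(id = 1:5, sire = c(0, 0, 1, 1, 3),
                    dam = c(0, 0, 2, 2, 4),
                    sex = c("M", "F", "M", "F", "M"),
                    generation = c(0, 0, 1, 1, 2))
  A <- pedigree_numerator_matrix(ped)
  expect_equal(A["1", "3"], 0.5)
  expect_equal(A["1", "2"], 0)
  expect_equal(A["3", "4"], 0.5)           # full sibs
  expect_equal(A["5", "5"], 1.25)          # offspring of full-sib mating
  expect_equal(A["1", "1"], 1)
  expect_equal(max(abs(A - t(A))), 0)
  # order of input rows must not matter
  A2 <- pedigree_numerator_matrix(ped[c(3, 1, 5, 2, 4), ])
  expect_equal(A2[rownames(A), colnames(A)], A, ignore_attr = TRUE)
})

test_that("relationship matrix TSV round-trips and validates symmetry", {
  G <- random_psd(6, 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_relationship_matrix(G, path)
  G2 <- read_relationship_matrix(path)
  expect_equal(unclass(G2), unclass(G), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(rownames(G2), rownames(G))
  # asymmetric input rejected
  bad <- G
  bad[1, 2] <- bad[1, 2] + 1
  write.table(data.frame(id = rownames(bad), bad), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_relationship_matrix(path), "symmetric")
})
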