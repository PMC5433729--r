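test_that("eigendecomposition reconstructs the matrix", {
  G <- diag(3)
  e <- eigendecompose(G)
  expect_equal(e$values, rep(1, 3))
  e2 <- eigendecompose(matrix(c(2, 0, 0, 1), 2))
  expect_equal(e2$values, c(2, 1))
  expect_equal(abs(e2$vectors[, 1]), c(1, 0))
  for (seed in 1:3) {
    G <- random_psd(5, seed)
    e <- eigendecompose(G)
    expect_lt(max(abs(e$vectors %*% diag(e$values) %*% t(e$vectors) - G)),
              1e-8)
    expect_equal(colSums(e$vectors^2), rep(1, 5), tolerance = 1e-8)
    expect_true(all(diff(e$values) <= 1e-12))
  }
  asym <- matrix(c(1, 0.5, 0.1, 1), 2)
  expect_error(eigendecompose(asym), "symmetric")
})

test_that("standardized eigenvectors whiten the matrix", {
  for (seed in 1:3) {
    G <- random_psd(6, seed + 10)
    e <- eigendecompose(G)
    S <- standardized_eigenvectors(e, 4)
    expect_equal(t(S) %*% G %*% S, diag(4), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  G <- diag(4)
  e <- eigendecompose(G)
  expect_equal(abs(standardized_eigenvectors(e, 2)), abs(e$vectors[, 1:2]))
  # rank-deficient guard
  X <- matrix(rnorm(12), 4, 3)
  e2 <- eigendecompose(tcrossprod(X))
  expect_error(standardized_eigenvectors(e2, 4), "tolerance")
})

test_that("contribution scores satisfy the algebraic identities", {
  for (seed in 1:4) {
    G <- random_psd(6, seed + 20)
    e <- eigendecompose(G)
    # k = n: gc equals diag(G) (r_ij = sqrt(lambda_i) u_ij)
    cs <- contribution_scores(G, 6, evd = e)
    expect_equal(unname(cs$gc), unname(diag(G)), tolerance = 1e-8)
    # conservation at any k
    for (k in c(2, 4)) {
      csk <- contribution_scores(G, k, evd = e)
      expect_equal(sum(csk$gc), sum(e$values[1:k]), tolerance = 1e-8)
      expect_true(all(csk$gc >= -1e-12))
    }
    # monotone growth in k
    gc2 <- contribution_scores(G, 2, evd = e)$gc
    gc3 <- contribution_scores(G, 3, evd = e)$gc
    expect_true(all(gc3 >= gc2 - 1e-12))
  }
})

test_that("ranking is equivariant under permutation of individuals", {
  G <- random_psd(12, 7)
  perm <- keycontrib:::with_seed(5, sample(12))
  Gp <- G[perm, perm]
  k <- 3
  r1 <- contribution_scores(G, k)
  r2 <- contribution_scores(Gp, k)
  expect_equal(sort(r2$gc[r1$ranking[1:k]]), sort(r1$gc[r1$ranking[1:k]]),
               tolerance = 1e-9)
  expect_setequal(r1$key_contributors, r2$key_contributors)
})

test_that("proportion of variance behaves like a cumulative fraction", {
  e <- eigendecompose(random_psd(8, 3))
  pv <- vapply(0:8, function(k) proportion_variance(e, k), numeric(1))
  expect_equal(pv[1], 0)
  expect_equal(pv[9], 1)
  expect_true(all(diff(pv) >= 0))
  expect_equal(proportion_variance(c(3, 1), 1), 0.75)
  # negative eigenvalues clamped in the denominator
  expect_equal(proportion_variance(c(3, 1, -1), 2), 1)
})

test_that("parallel analysis recovers constructed block structure", {
  # b equal noiseless blocks span b - 1 contrast components once columns
  # are centered and standardized (the relationship profiles of the b
  # groups sum to a constant), so data-matrix parallel analysis retains
  # exactly b - 1 components on this degenerate fixture
  for (b in c(3, 5)) {
    G <- block_matrix(b, 20, 0.5)
    pa <- significant_components(G, iterations = 40, seed = 2)
    expect_equal(pa$k, b - 1)
    pa_mp <- significant_components(G, null = "marchenko")
    expect_equal(pa_mp$k, b - 1)
  }
  # the permutation null compares G's own eigenvalues, where all 3 block
  # eigenvalues (1 + 19 * 0.5 = 10.5) dominate the structure-free GRM null
  G <- block_matrix(3, 20, 0.5)
  geno <- keycontrib:::with_seed(4, {
    matrix(rbinom(500 * 60, 2, 0.5), 500, 60)
  })
  pa_perm <- significant_components(G, geno, iterations = 40,
                                    null = "permutation", seed = 2)
  expect_equal(pa_perm$k, 3)
})

test_that("parallel analysis retains little under a structure-free null", {
  map <- snp_map(2, 500, 50)
  fh <- simulate_founder_haplotypes(map, n_founders = 100, seed = 6)
  G <- allele_sharing_grm(dosage_matrix(fh))
  pa <- significant_components(G, iterations = 40, seed = 3)
  expect_lte(pa$k, 5)   # <= 0.05 * n
  # permutation null consistency on its own scale
  pa2 <- significant_components(G, dosage_matrix(fh), iterations = 40,
                                null = "permutation", seed = 3)
  expect_lte(pa2$k, 5)
})

test_that("marchenko rank quantiles match the Monte-Carlo null", {
  n <- 120
  q_mp <- keycontrib:::mp_rank_quantiles(n, 1)
  null_ev <- keycontrib:::with_seed(9, {
    vapply(1:60, function(i) {
      X <- matrix(rnorm(n * n), n, n)
      eigen(keycontrib:::cor_fast(X), symmetric = TRUE,
            only.values = TRUE)$values
    }, numeric(n))
  })
  mc_mean <- rowMeans(null_ev)
  expect_lt(max(abs(q_mp[5:100] - mc_mean[5:100])), 0.15)
})

test_that("key contributors wrapper recovers designed founders", {
  pop <- small_pop()
  ped <- pop$pedigree
  G <- ibd_grm(pop$haplotypes)
  kc <- key_contributors(G, iterations = 40, seed = 4)
  sires <- ped$id[ped$generation == 0 & ped$sex == "M"]
  # 4 designed families: 3-4 components (the noiseless-block limit is 3)
  expect_true(kc$parallel_analysis$k %in% c(3L, 4L))
  expect_setequal(head(kc$contribution$ranking, 4), sires)
  expect_equal(kc$proportion_variance,
               proportion_variance(kc$parallel_analysis,
                                   kc$parallel_analysis$k))
  expect_gt(kc$proportion_variance, 0.3)
  df <- as.data.frame(kc$contribution)
  expect_equal(df$id[df$rank == 1], kc$contribution$ranking[1])
  expect_equal(sum(df$is_key_contributor), kc$parallel_analysis$k)
})
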