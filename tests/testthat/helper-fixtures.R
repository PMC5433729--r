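# Shared fixtures, simulated once per test run and cached.

fixture_env <- new.env(parent = emptyenv())

# A reduced two-generation breeding design: 4 sires x 40 dams, 2
# chromosomes x 500 SNPs. Same mating rules as the full design, desk scale.
small_pop <- function() {
  if (is.null(fixture_env$small)) {
    fixture_env$small <- simulate_population(
      n_generations = 2, seed = 42, n_chrom = 2, snps_per_chrom = 500,
      n_males = 4, n_females = 40, n_double_dams = 4)
  }
  fixture_env$small
}

# Three-generation variant used for selection / phasing comparisons.
medium_pop <- function() {
  if (is.null(fixture_env$medium)) {
    fixture_env$medium <- simulate_population(
      n_generations = 3, seed = 99, n_chrom = 3, snps_per_chrom = 400,
      n_males = 5, n_females = 50, n_double_dams = 5)
  }
  fixture_env$medium
}

# Random PSD matrix with unit-scale diagonal.
random_psd <- function(n, seed) {
  with_seed <- keycontrib:::with_seed
  with_seed(seed, {
    X <- matrix(rnorm(n * (n + 5)), n)
    G <- tcrossprod(X) / (n + 5)
    dimnames(G) <- list(as.character(seq_len(n)), as.character(seq_len(n)))
    G
  })
}

# Block-diagonal relationship matrix: `blocks` families of size `size`
# with within-family relationship `rho`.
block_matrix <- function(blocks, size, rho) {
  n <- blocks * size
  G <- matrix(0, n, n)
  for (b in seq_len(blocks)) {
    idx <- ((b - 1) * size + 1):(b * size)
    G[idx, idx] <- rho
  }
  diag(G) <- 1
  dimnames(G) <- list(as.character(seq_len(n)), as.character(seq_len(n)))
  G
}
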