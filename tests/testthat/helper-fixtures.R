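# Fixtures are built in code so tests carry no data files.

# Six-sample two-SNP toy set whose 9x2 table is hand-counted in the tests.
toy6 <- function() {
  g <- rbind(c(0L, 0L), c(0L, 1L), c(1L, 1L), c(2L, 1L), c(0L, 0L), c(2L, 2L))
  genotype_data(g, phenotype = c(1L, 1L, 0L, 0L, 0L, 1L))
}

# Dataset where the phenotype is a deterministic XOR-like function of the
# first two SNPs: y = (g1 + g2) mod 2. The pair (1, 2) fixes y exactly.
xor_data <- function(n = 120L, p = 4L, seed = 11L) {
  set.seed(seed)
  G <- matrix(sample(0:2, n * p, replace = TRUE), n, p)
  y <- (G[, 1L] + G[, 2L]) %% 2L
  # guarantee both classes
  if (length(unique(y)) < 2L) stop("degenerate xor fixture")
  genotype_data(G, phenotype = y)
}

# Random null dataset: independent HWE-free uniform genotypes, balanced y.
random_data <- function(n = 100L, p = 6L, seed = 1L) {
  set.seed(seed)
  G <- matrix(sample(0:2, n * p, replace = TRUE), n, p)
  genotype_data(G, phenotype = rep(0:1, length.out = n))
}

# Random 3^k x 2 count table with both phenotype classes present.
random_table <- function(k, lambda = 6) {
  m <- 3L^k
  repeat {
    tab <- matrix(stats::rpois(2L * m, lambda), nrow = m)
    if (all(colSums(tab) > 0)) return(tab)
  }
}

# Independent oracle for R0 built from first principles (no shared code
# with the scan machinery): explicit probability sums over the table.
oracle_r0 <- function(tab) {
  n <- sum(tab)
  py <- colSums(tab) / n
  H_Y <- -sum(ifelse(py > 0, py * log2(py), 0))
  px <- rowSums(tab) / n
  H_YX <- 0
  for (g in seq_len(nrow(tab))) {
    if (px[g] == 0) next
    pc <- tab[g, ] / sum(tab[g, ])
    H_YX <- H_YX + px[g] * -sum(ifelse(pc > 0, pc * log2(pc), 0))
  }
  (H_Y - H_YX) / H_Y
}

# Brute-force R0 for one SNP combination of a dataset, via the public
# single-table path (used as the oracle for the vectorized scan).
brute_r0 <- function(data, snps) {
  relative_information_gain(contingency_table(data, snps))$R0
}
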