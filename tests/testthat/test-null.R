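test_that("phenotype permutation preserves margins, genotypes and seeds", {
  d <- random_data(n = 60, p = 4, seed = 4)
  set.seed(1); p1 <- permute_phenotype(d)
  expect_identical(sum(p1$phenotype), sum(d$phenotype))
  expect_identical(p1$genotypes, d$genotypes)
  expect_identical(p1$snp_ids, d$snp_ids)
  set.seed(1); p2 <- permute_phenotype(d)
  expect_identical(p1$phenotype, p2$phenotype)
})

test_that("the permutation null reproduces a brute-force ensemble exactly", {
  d <- random_data(n = 50, p = 4, seed = 6)
  nul <- rig_null(d, order = 2, n_perm = 5, seed = 123)
  # independent loop: same shuffles, max over all pairs via the
  # single-table path
  set.seed(123)
  M_ref <- replicate(5, {
    d2 <- d
    d2$phenotype <- sample(d$phenotype)
    max(utils::combn(4, 2, function(ix) brute_r0(d2, ix)))
  })
  expect_equal(nul$M, M_ref, tolerance = 1e-12)
  expect_equal(nul$mu, mean(M_ref))
  expect_equal(nul$sigma, stats::sd(M_ref))   # unbiased (n-1) denominator
  expect_identical(nul$n_perm, 5L)
  # fixed seed reproduces the ensemble
  expect_equal(rig_null(d, order = 2, n_perm = 5, seed = 123)$M, nul$M)
})

test_that("constant genotypes give a degenerate-null error", {
  d <- genotype_data(matrix(1L, 40, 3), phenotype = rep(0:1, 20))
  expect_error(rig_null(d, order = 2, n_perm = 10, seed = 1), "degenerate null")
})

test_that("the null of the maximum shifts right with interaction order", {
  d <- random_data(n = 200, p = 6, seed = 31)
  n1 <- rig_null(d, order = 1, n_perm = 100, seed = 7)
  n2 <- rig_null(d, order = 2, n_perm = 100, seed = 7)
  expect_gt(n2$mu, n1$mu)
})

test_that("standardization is the stated affine map and preserves ranks", {
  d <- random_data(n = 80, p = 5, seed = 12)
  s <- scan_rig(d, order = 2)
  nul <- rig_null(d, order = 2, n_perm = 60, seed = 3)
  z <- standardize_rig(s, nul)
  expect_equal(z$U_r, (s$R0 - nul$mu) / nul$sigma)
  expect_identical(order(-z$U_r), order(-z$R0))
  expect_equal(stats::cor(rank(z$R0), rank(z$U_r), method = "spearman"), 1)
  # R0 at mu maps to 0, at mu + sigma maps to 1
  fake <- s[1:2, ]; fake$R0 <- c(nul$mu, nul$mu + nul$sigma)
  attr(fake, "order") <- 2L
  zf <- standardize_rig(fake, nul)
  expect_equal(zf$U_r, c(0, 1))
  # order mismatch is refused
  nul1 <- rig_null(d, order = 1, n_perm = 10, seed = 3)
  expect_error(standardize_rig(s, nul1), "order mismatch")
})

test_that("adjusted p-values are max-statistic exceedance fractions", {
  nul <- structure(list(order = 2L, n_perm = 4L, M = c(0.1, 0.2, 0.3, 0.4),
                        mu = 0.25, sigma = stats::sd(c(0.1, 0.2, 0.3, 0.4)),
                        n_combinations = 10L, seed = NA_integer_),
                   class = "rig_null")
  expect_equal(adjusted_pvalue(0.25, nul), 0.5)
  expect_equal(adjusted_pvalue(0.05, nul), 1.0)   # below every M_i
  expect_equal(adjusted_pvalue(0.99, nul), 0.0)   # above every M_i
  expect_equal(adjusted_pvalue(0.2, nul), 0.75)   # ties counted (>=)
  expect_match(rigscan:::format_pvalue(0, 1000), "< 0.001")
})

test_that("cutoffs use the conservative upper order statistic", {
  M <- sample(1:100) / 100
  nul <- structure(list(order = 2L, n_perm = 100L, M = M, mu = mean(M),
                        sigma = stats::sd(M), n_combinations = 45L,
                        seed = NA_integer_), class = "rig_null")
  cut <- rig_cutoff(nul, alpha = 0.05)
  expect_equal(cut$M_cut, 0.95)                       # 95th smallest of 1..100
  expect_equal(cut$U_cut, (0.95 - nul$mu) / nul$sigma)
  expect_equal(rig_cutoff(nul, alpha = 0.5)$M_cut, sort(M)[50])
  expect_error(rig_cutoff(nul, alpha = 0), "alpha")
  expect_error(rig_cutoff(nul, alpha = 0.005), "resolve")
})

test_that("the cutoff rule and the p-value rule flag the same combinations", {
  d <- random_data(n = 120, p = 6, seed = 17)
  s <- scan_rig(d, order = 2)
  # n_perm * alpha = 7.5 is non-integral, so the two decision rules agree
  # away from exact ties between R0 and an M_i
  nul <- rig_null(d, order = 2, n_perm = 150, seed = 5)
  z <- standardize_rig(s, nul)
  cut <- rig_cutoff(nul, alpha = 0.05)
  expect_identical(z$R0 > cut$M_cut, z$p_adj < 0.05)
})

test_that("permuted-data maxima standardize to zero mean and unit spread", {
  d <- random_data(n = 100, p = 5, seed = 19)
  nul <- rig_null(d, order = 2, n_perm = 300, seed = 23)
  set.seed(57)
  z <- replicate(150, {
    dp <- permute_phenotype(d)
    (scan_rig(dp, order = 2, top_n = 1)$R0[1] - nul$mu) / nul$sigma
  })
  expect_lt(abs(mean(z)), 0.25)
  expect_gt(stats::sd(z), 0.7)
  expect_lt(stats::sd(z), 1.4)
})

test_that("null summaries round-trip through JSON", {
  d <- random_data(n = 60, p = 4, seed = 2)
  nul <- rig_null(d, order = 2, n_perm = 40, seed = 14)
  path <- tempfile(fileext = ".json")
  write_null_json(nul, path)
  back <- read_null_json(path)
  expect_identical(back$order, nul$order)
  expect_identical(back$n_perm, nul$n_perm)
  expect_equal(back$mu, nul$mu)
  expect_equal(back$sigma, nul$sigma)
  expect_equal(back$M, nul$M)
  # a re-imported null standardizes a scan identically
  s <- scan_rig(d, order = 2)
  expect_equal(standardize_rig(s, back)$U_r, standardize_rig(s, nul)$U_r)
})
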