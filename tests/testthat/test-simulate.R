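test_that("penetrance derivation satisfies its defining constraints", {
  # flat odds ratios: closed form, every penetrance equals the prevalence
  flat <- derive_penetrance(matrix(1, 3, 3), maf = 0.2, prevalence = 0.05)
  expect_equal(unname(flat$penetrance), matrix(0.05, 3, 3), tolerance = 1e-10)
  expect_equal(flat$baseline_odds, 0.05 / 0.95, tolerance = 1e-8)

  for (mid in 1:8) {
    m <- penetrance_model(mid)
    w <- outer(hwe_genotype_freq(m$maf), hwe_genotype_freq(m$maf))
    # HWE-weighted mean penetrance reproduces the model prevalence
    expect_equal(sum(w * m$penetrance), m$prevalence, tolerance = 1e-8)
    expect_true(all(m$penetrance >= 0 & m$penetrance < 1))
    # odds ratios reproduce as odds(penetrance) / baseline odds
    pos <- m$or_table > 0
    odds <- m$penetrance / (1 - m$penetrance)
    expect_equal(odds[pos] / m$baseline_odds, m$or_table[pos], tolerance = 1e-8)
    expect_true(all(m$penetrance[!pos] == 0))   # structural zeros
  }
  expect_error(derive_penetrance(matrix(1, 3, 3), maf = 0.6, prevalence = 0.05), "maf")
  expect_error(derive_penetrance(matrix(-1, 3, 3), 0.1, 0.05), "positive")
})

test_that("the solved baseline odds matches a dense grid search", {
  grid <- 10^seq(log10(1e-8), log10(1e3), length.out = 1e6)
  for (mid in 1:8) {
    m <- penetrance_model(mid)
    w <- as.numeric(outer(hwe_genotype_freq(m$maf), hwe_genotype_freq(m$maf)))
    or <- as.numeric(m$or_table)
    prev <- numeric(length(grid))
    for (c in seq_along(or))
      prev <- prev + w[c] * or[c] * grid / (1 + or[c] * grid)
    b_grid <- grid[which.min(abs(prev - m$prevalence))]
    expect_equal(m$baseline_odds, b_grid, tolerance = 5e-4)
  }
})

test_that("causal-pair sampling follows the retrospective distribution", {
  # flat penetrance: case genotypes are plain HWE draws
  flat <- derive_penetrance(matrix(1, 3, 3), maf = 0.3, prevalence = 0.1)
  set.seed(61)
  g <- sample_causal_pair(flat, "case", 1e5)
  w <- outer(hwe_genotype_freq(0.3), hwe_genotype_freq(0.3))  # [B, A]
  obs <- table(factor(g[, "B"], 0:2), factor(g[, "A"], 0:2))
  expect_gt(stats::chisq.test(as.numeric(obs), p = as.numeric(w))$p.value, 0.01)

  # one-cell penetrance: every case lands in that cell
  or1 <- matrix(0, 3, 3); or1[2, 2] <- 1
  det <- derive_penetrance(or1, maf = 0.25, prevalence = 0.01)
  gd <- sample_causal_pair(det, "case", 500)
  expect_true(all(gd[, "A"] == 1L & gd[, "B"] == 1L))

  # model 1 cases against the analytic conditional distribution
  m1 <- penetrance_model(1)
  w1 <- outer(hwe_genotype_freq(m1$maf), hwe_genotype_freq(m1$maf))
  pcell <- w1 * m1$penetrance; pcell <- pcell / sum(pcell)
  set.seed(62)
  g1 <- sample_causal_pair(m1, "case", 1e5)
  obs1 <- table(factor(g1[, "B"], 0:2), factor(g1[, "A"], 0:2))
  keep <- as.numeric(pcell) > 0
  expect_gt(suppressWarnings(stats::chisq.test(
    as.numeric(obs1)[keep], p = as.numeric(pcell)[keep])$p.value), 0.01)
})

test_that("forward population simulation recovers each model's prevalence", {
  set.seed(70)
  n <- 2e5L
  for (mid in 1:8) {
    m <- penetrance_model(mid)
    gA <- stats::rbinom(n, 2L, m$maf)
    gB <- stats::rbinom(n, 2L, m$maf)
    disease <- stats::rbinom(n, 1L, m$penetrance[cbind(gB + 1L, gA + 1L)])
    se <- sqrt(m$prevalence * (1 - m$prevalence) / n)
    expect_lt(abs(mean(disease) - m$prevalence), 3 * se)
  }
})

test_that("prospective odds ratios converge to the model grid", {
  set.seed(71)
  m <- penetrance_model(1)
  n <- 4e5L
  gA <- stats::rbinom(n, 2L, m$maf)
  gB <- stats::rbinom(n, 2L, m$maf)
  disease <- stats::rbinom(n, 1L, m$penetrance[cbind(gB + 1L, gA + 1L)])
  w <- outer(hwe_genotype_freq(m$maf), hwe_genotype_freq(m$maf))
  for (i in 1:3) for (j in 1:3) {
    if (w[i, j] * n < 5000) next                    # skip sparse cells
    in_cell <- gB == (i - 1L) & gA == (j - 1L)
    p_hat <- mean(disease[in_cell])
    or_hat <- (p_hat / (1 - p_hat)) / m$baseline_odds
    expect_equal(or_hat, m$or_table[i, j], tolerance = 0.1)
  }
})

test_that("simulated datasets have the declared design and determinism", {
  d <- simulate_case_control(group = 1, model = 3, seed = 5)
  expect_identical(dim(d), c(400L, 10L))
  expect_identical(sum(d$phenotype), 200L)
  expect_identical(attr(d, "causal"), c(1L, 2L))
  d2 <- simulate_case_control(group = 1, model = 3, seed = 5)
  expect_identical(d$genotypes, d2$genotypes)
  expect_identical(d$phenotype, d2$phenotype)
  # group mapping crosses panels and sample sizes as designed
  expect_identical(simulation_design(1)[c("n_snp", "n_sample")],
                   list(n_snp = 10L, n_sample = 400L))
  expect_identical(simulation_design(8)[c("n_snp", "n_sample")],
                   list(n_snp = 100L, n_sample = 1000L))
  expect_identical(simulation_design(15)[c("n_snp", "n_sample")],
                   list(n_snp = 1000L, n_sample = 2000L))
  expect_error(simulation_design(16), "group")
  expect_error(simulate_case_control(n_sample = 401), "even")
  # fixed-MAF noise scheme
  dn <- simulate_case_control(n_snp = 5, n_sample = 100, maf_noise = 0.3, seed = 1)
  expect_true(all(attr(dn, "maf") == 0.3))
})

test_that("null-generator maxima are exchangeable with permutation maxima", {
  # top R0 of independent null datasets vs the permutation-null M of one
  # such dataset: same distribution
  tops <- vapply(1:60, function(i) {
    d <- simulate_case_control(n_snp = 6, n_sample = 200, model = NULL,
                               seed = 300 + i)
    scan_rig(d, order = 2, top_n = 1)$R0[1]
  }, numeric(1))
  d0 <- simulate_case_control(n_snp = 6, n_sample = 200, model = NULL, seed = 299)
  M <- rig_null(d0, order = 2, n_perm = 60, seed = 17)$M
  expect_gt(stats::wilcox.test(tops, M)$p.value, 0.01)
})

test_that("under the global null every pair is equally likely to win", {
  set.seed(83)
  hits <- 0L
  n_rep <- 90L
  for (i in seq_len(n_rep)) {
    d <- simulate_case_control(n_snp = 10, n_sample = 200, model = NULL,
                               seed = 5000 + i)
    top <- sort(attr(scan_rig(d, order = 2, top_n = 1), "indices")[, 1])
    hits <- hits + all(top == c(1L, 2L))
  }
  # binomial(90, 1/45): mean 2, sd 1.4
  expect_lte(hits, 8L)
})

test_that("hit ratios by R0 and by U_r are identical by rank invariance", {
  # standardization is monotone, so the winning pair is the same under
  # either score; check directly on a handful of replicates
  for (i in 1:5) {
    d <- simulate_case_control(n_snp = 6, n_sample = 200, model = 1,
                               seed = 900 + i)
    s <- scan_rig(d, order = 2)
    nul <- rig_null(d, order = 2, n_perm = 30, seed = i)
    z <- standardize_rig(s, nul)
    expect_identical(z$combo[which.max(z$U_r)], s$combo[which.max(s$R0)])
  }
})

test_that("the power experiment reports per-cell hit ratios with provenance", {
  tab <- power_experiment(models = 1, groups = 1, n_replicates = 4,
                          methods = c("U_r", "MDR_BA"), seed = 12)
  expect_identical(nrow(tab), 2L)
  expect_true(all(tab$hit_ratio >= 0 & tab$hit_ratio <= 1))
  expect_identical(tab$n_snp, rep(10L, 2)); expect_identical(tab$n_sample, rep(400L, 2))
  # reproducible under the master seed
  tab2 <- power_experiment(models = 1, groups = 1, n_replicates = 4,
                           methods = c("U_r", "MDR_BA"), seed = 12)
  expect_identical(tab$hits, tab2$hits)
})
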