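test_that("IBS counts follow allele-sharing arithmetic", {
  expect_equal(ibs_counts(c(0, 1, 2), c(0, 1, 2)),
               c(ibs0 = 0, ibs1 = 0, ibs2 = 3))
  expect_equal(ibs_counts(c(0, 0, 2), c(2, 2, 0)),
               c(ibs0 = 3, ibs1 = 0, ibs2 = 0))
  expect_equal(ibs_counts(c(1, 0, 2), c(0, 1, 1)),
               c(ibs0 = 0, ibs1 = 3, ibs2 = 0))
  # missing genotypes are excluded; counts sum to SNPs used
  expect_equal(sum(ibs_counts(c(1, NA, 2), c(0, 1, NA))), 1)
  expect_error(ibs_counts(c(NA, NA), c(1, 2)), "non-missing")
})

test_that("a duplicated sample estimates PI_HAT of 1", {
  set.seed(1)
  p <- simulate_snp_panel("duplicate", 2000)
  expect_identical(p$geno[, 1], p$geno[, 2])
  est <- estimate_ibd(p$geno[, 1], p$geno[, 2], p$freq)
  expect_equal(est$pi_hat, 1, tolerance = 1e-6)
})

test_that("the estimator is symmetric in the pair", {
  set.seed(2)
  p <- simulate_snp_panel("full_sibs", 3000)
  a <- estimate_ibd(p$geno[, 1], p$geno[, 2], p$freq)
  b <- estimate_ibd(p$geno[, 2], p$geno[, 1], p$freq)
  expect_equal(a, b)
})

test_that("parent-offspring pairs estimate Z0 near 0 and PI_HAT near 0.5", {
  set.seed(3)
  ests <- replicate(50, {
    p <- simulate_snp_panel("parent_offspring", 5000)
    est <- estimate_ibd(p$geno[, 1], p$geno[, 2], p$freq)
    c(est$z0, est$pi_hat)
  })
  expect_lt(max(ests[1, ]), 0.02)          # PO pairs share >= 1 allele IBD
  expect_equal(mean(ests[2, ]), 0.5, tolerance = 0.02)
})

test_that("full-sibling pairs estimate (Z0, Z1, Z2) near (1/4, 1/2, 1/4)", {
  set.seed(4)
  zs <- replicate(20, {
    p <- simulate_snp_panel("full_sibs", 5000)
    est <- estimate_ibd(p$geno[, 1], p$geno[, 2], p$freq)
    c(est$z0, est$z1, est$z2)
  })
  expect_equal(unname(rowMeans(zs)), c(0.25, 0.5, 0.25), tolerance = 0.03)
})

test_that("unrelated pairs estimate PI_HAT near 0", {
  set.seed(5)
  for (i in 1:5) {
    p <- simulate_snp_panel("unrelated", 10000)
    est <- estimate_ibd(p$geno[, 1], p$geno[, 2], p$freq)
    expect_lt(est$pi_hat, 0.05)
  }
})

test_that("IBD components are clamped, normalized and bounded", {
  set.seed(6)
  for (rel in c("parent_offspring", "full_sibs", "unrelated")) {
    p <- simulate_snp_panel(rel, 1000)
    est <- estimate_ibd(p$geno[, 1], p$geno[, 2], p$freq)
    z <- c(est$z0, est$z1, est$z2)
    expect_true(all(z >= 0 & z <= 1))
    expect_equal(sum(z), 1, tolerance = 1e-12)
    expect_gte(est$pi_hat, 0)
    expect_lte(est$pi_hat, 1)
  }
})

test_that("low-MAF SNPs are pruned and degenerate panels rejected", {
  set.seed(7)
  g <- matrix(rbinom(400, 2, 0.3), ncol = 2)
  freq <- c(rep(0.3, 150), rep(0.01, 50))
  est <- estimate_ibd(g[, 1], g[, 2], freq)
  expect_equal(est$n_snps_used, 150)
  expect_error(estimate_ibd(g[, 1], g[, 2], rep(0.001, 200)),
               "degenerate")
})

test_that("the variant-set wrapper reports the PLINK-style columns", {
  set.seed(8)
  sim <- simulate_cohort(sim_config(seed = 8, n_background = 300), tempfile())
  x <- sim$variant_set
  tab <- estimate_ibd_pairs(x, data.frame(a = "FA", b = "DA"), min_maf = 0.05)
  expect_named(tab, c("sample1", "sample2", "Z0", "Z1", "Z2", "PI_HAT", "NSNP"))
  expect_true(tab$PI_HAT >= 0 && tab$PI_HAT <= 1)
  expect_error(estimate_ibd_pairs(x, data.frame("FA", "NOBODY")),
               "unknown sample")
})
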