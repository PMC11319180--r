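test_that("significance filter keeps strictly sub-threshold records in order", {
  tab <- make_gwas(c("rs1", "rs2", "rs3"), beta = 0.1, se = 0.01,
                   pval = c(1e-9, 5e-8, 4e-8))
  got <- select_by_pvalue(tab, 5e-8)
  expect_equal(got$snp_id, c("rs1", "rs3"))  # 5e-8 itself is excluded
  expect_equal(nrow(select_by_pvalue(tab[0, ], 5e-8)), 0L)
  expect_equal(select_by_pvalue(tab, 0.9), tab)
})

test_that("clumping follows the greedy smallest-p rule", {
  # 5,000 kb apart with r2 = 0.5 > 0.001: only the smaller p survives
  two <- make_gwas(c("rs1", "rs2"), beta = 0.1, se = 0.01,
                   pval = c(1e-9, 1e-10), pos = c(1e6, 1e6 + 5e6))
  ld <- data.frame(snp_a = "rs1", snp_b = "rs2", r2 = 0.5)
  got <- clump(two, r2_max = 0.001, window_kb = 10000, ld = ld)
  expect_equal(got$snp_id, "rs2")
  # 20,000 kb apart at a 10,000 kb window: both survive
  far <- make_gwas(c("rs1", "rs2"), beta = 0.1, se = 0.01,
                   pval = c(1e-9, 1e-10), pos = c(1e6, 1e6 + 2e7))
  expect_equal(nrow(clump(far, ld = ld)), 2L)
  # five mutually-within-window SNPs, distance-only: one survivor
  five <- make_gwas(sprintf("rs%d", 1:5), beta = 0.1, se = 0.01,
                    pval = c(1e-8, 1e-12, 1e-9, 1e-10, 1e-11),
                    pos = seq(1e6, by = 1e6, length.out = 5))
  got5 <- clump(five)
  expect_equal(got5$snp_id, "rs2")
})

test_that("clump output is independent of input ordering", {
  set.seed(7)
  tab <- make_gwas(sprintf("rs%02d", 1:12), beta = 0.1, se = 0.01,
                   pval = runif(12, 1e-12, 1e-8),
                   chrom = rep(c("1", "2"), each = 6),
                   pos = rep(seq(1e6, by = 4e6, length.out = 6), 2))
  a <- clump(tab)
  b <- clump(tab[sample(nrow(tab)), ])
  expect_equal(a, b)
  # equal p-values break ties on the lexicographically smaller snp_id
  tie <- make_gwas(c("rs9", "rs1"), beta = 0.1, se = 0.01,
                   pval = c(1e-9, 1e-9), pos = c(1e6, 2e6))
  expect_equal(clump(tie)$snp_id, "rs1")
})

test_that("instrument strength matches the closed-form derivation", {
  st <- strength_stats(0.1, 0.01, 0.3, 7174, k = 1)
  expect_equal(st$r2, 0.013748, tolerance = 1e-4)
  expect_equal(st$f_stat, 99.97, tolerance = 1e-3)
  expect_equal(strength_stats(0, 0.01, 0.3, 7174)$r2, 0)
  expect_equal(strength_stats(0, 0.01, 0.3, 7174)$f_stat, 0)
  # doubling the se strictly decreases both statistics
  lo <- strength_stats(0.1, 0.02, 0.3, 7174)
  expect_lt(lo$r2, st$r2)
  expect_lt(lo$f_stat, st$f_stat)
  expect_error(strength_stats(0.1, 0.01, NA, 7174), "eaf")
  expect_error(strength_stats(0.1, 0.01, 0.3, 2, k = 1), "sample size")
})

test_that("strength statistics agree with an algebraic re-derivation", {
  # the printed R2 simplifies to beta^2 / (beta^2 + N se^2): MAF cancels
  set.seed(11)
  for (i in 1:1000) {
    beta <- rnorm(1, 0, 0.3)
    se <- runif(1, 0.005, 0.05)
    eaf <- runif(1, 0.01, 0.99)
    n <- sample(2000:500000, 1)
    k <- sample(1:10, 1)
    got <- strength_stats(beta, se, eaf, n, k)
    r2 <- beta^2 / (beta^2 + n * se^2)
    expect_equal(got$r2, r2, tolerance = 1e-12)
    expect_equal(got$f_stat, r2 / (1 - r2) * (n - k - 1) / k,
                 tolerance = 1e-12)
  }
})

test_that("outcome-associated instruments are excluded strictly", {
  tab <- make_harmonized(3, seed = 1)
  tab$pval_out <- c(1e-6, 5e-5, 0.5)
  got <- exclude_outcome_associated(tab, threshold = 5e-5)
  expect_equal(got$snp_id, tab$snp_id[2:3])  # exactly 5e-5 is retained
  expect_equal(attr(got, "removed"), tab$snp_id[1])
  all_clear <- exclude_outcome_associated(tab, threshold = 1e-7)
  expect_equal(all_clear$snp_id, tab$snp_id)
  tab$pval_out[2] <- NA
  expect_error(exclude_outcome_associated(tab), "outcome p-value")
})

test_that("build_instrument_set applies the full cascade with attrition logging", {
  truth <- simulation_truth(theta = 0, j_snps = 12, seed = 303,
                            gamma_range = c(0.3, 0.4),
                            maf_range = c(0.2, 0.5))
  sim <- simulate_two_sample(truth)
  set <- build_instrument_set(sim$discovery$exposure,
                              sim$discovery$outcome,
                              exposure_id = "lipid1", outcome_id = "ICH")
  expect_true(set$eligible)
  expect_equal(nrow(set$instruments), 12L)
  at <- set$attrition
  expect_true(all(at$n_in - at$n_removed == at$n_out))
  expect_equal(at$n_out[nrow(at)], nrow(set$instruments))
  # strength columns are populated with k = final count
  expect_true(all(set$instruments$f_stat > 10))
  k <- nrow(set$instruments)
  manual <- strength_stats(set$instruments$beta_exp,
                           set$instruments$se_exp,
                           set$instruments$eaf_exp,
                           set$instruments$n_exp, k = k)
  expect_equal(set$instruments$f_stat, manual$f_stat)
})

test_that("sets below the two-instrument rule are ineligible", {
  # nothing reaches genome-wide significance
  weak <- make_gwas(sprintf("rs%d", 1:5), beta = 0.01, se = 0.01,
                    pval = rep(1e-4, 5))
  outc <- make_gwas(sprintf("rs%d", 1:5), beta = 0, se = 0.01, pval = 0.5)
  set <- build_instrument_set(weak, outc)
  expect_false(set$eligible)
  expect_equal(nrow(set$instruments), 0L)
  expect_equal(set$attrition$n_removed[1], 5L)  # attrition at significance
  # exactly one survivor is still ineligible and MR refuses the set
  one <- make_gwas("rs1", beta = 0.3, se = 0.01, pval = 1e-20)
  set1 <- build_instrument_set(one, outc)
  expect_false(set1$eligible)
  expect_error(mr_estimate_all(set1, seed = 1), "fewer than two")
})
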