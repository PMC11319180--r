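test_that("Wald ratio arithmetic, zero case, and sign symmetry", {
  w <- wald_ratio(0.10, 0.02, 0.01)
  expect_equal(w$ratio, 0.2)
  expect_equal(w$se, 0.1)
  expect_equal(wald_ratio(0.1, 0, 0.01)$ratio, 0)
  expect_equal(wald_ratio(-0.1, -0.02, 0.01)$ratio, 0.2)
  expect_error(wald_ratio(0, 0.02, 0.01), "beta_exp")
})

test_that("IVW pools ratios with inverse-variance weights", {
  tab <- make_harmonized(2, seed = 1)
  tab$beta_exp <- c(1, 1); tab$se_exp <- 1e-6
  tab$beta_out <- c(0.2, 0.4); tab$se_out <- c(0.1, 0.1)
  fe <- mr_ivw(tab, "FE")
  expect_equal(fe$beta, 0.3)
  expect_equal(fe$se, sqrt(1 / 200), tolerance = 1e-10)
  # identical ratios: Q = 0, MRE collapses onto FE
  tab$beta_out <- c(0.3, 0.3)
  mre <- mr_ivw(tab, "MRE")
  expect_equal(mre$beta, mr_ivw(tab, "FE")$beta)
  expect_equal(mre$se, mr_ivw(tab, "FE")$se)
})

test_that("IVW equals weighted least squares through the origin", {
  set.seed(5)
  for (i in 1:200) {
    tab <- make_harmonized(sample(3:15, 1), theta = runif(1, -0.5, 0.5),
                           seed = i)
    fe <- mr_ivw(tab, "FE")
    wls <- lm(beta_out ~ beta_exp - 1, data = tab,
              weights = 1 / tab$se_out^2)
    expect_equal(fe$beta, unname(coef(wls)[1]), tolerance = 1e-12)
    # and equals the fixed-effect meta-analysis of the Wald ratios
    oracle <- ivw_meta_oracle(tab)
    expect_equal(fe$beta, oracle$beta, tolerance = 1e-12)
    expect_equal(fe$se, oracle$se, tolerance = 1e-12)
    # MRE never undercuts FE
    expect_gte(mr_ivw(tab, "MRE")$se, fe$se)
  }
})

test_that("exposure rescaling divides every estimator by the scale factor", {
  tab <- make_harmonized(8, theta = 0.25, seed = 9)
  scaled <- tab
  c0 <- 2.5
  scaled$beta_exp <- c0 * tab$beta_exp
  scaled$se_exp <- c0 * tab$se_exp
  expect_equal(mr_ivw(scaled, "FE")$beta, mr_ivw(tab, "FE")$beta / c0)
  expect_equal(mr_egger(scaled)$beta, mr_egger(tab)$beta / c0)
  expect_equal(mr_weighted_median(scaled, 50, seed = 1)$beta,
               mr_weighted_median(tab, 50, seed = 1)$beta / c0)
  expect_equal(mr_weighted_mode(scaled, 1, 50, seed = 1)$beta,
               mr_weighted_mode(tab, 1, 50, seed = 1)$beta / c0,
               tolerance = 1e-6)
})

test_that("Egger regression recovers slope and intercept on noiseless data", {
  tab <- make_harmonized(5, seed = 3)
  tab$beta_exp <- seq(0.1, 0.5, by = 0.1)
  tab$se_out <- 0.01
  tab$beta_out <- 0.5 * tab$beta_exp
  fit <- mr_egger(tab)
  expect_equal(fit$beta, 0.5, tolerance = 1e-10)
  expect_equal(fit$egger_intercept, 0, tolerance = 1e-10)
  expect_equal(fit$egger_intercept_p, 1)
  tab$beta_out <- 0.5 * tab$beta_exp + 0.01
  fit2 <- mr_egger(tab)
  expect_equal(fit2$egger_intercept, 0.01, tolerance = 1e-10)
  expect_error(mr_egger(make_harmonized(2, seed = 1)), "three")
})

test_that("Egger with its intercept constrained to zero reproduces IVW", {
  set.seed(21)
  for (i in 1:20) {
    tab <- make_harmonized(sample(4:12, 1), theta = 0.2, seed = 100 + i)
    flip <- sign(tab$beta_exp)
    x <- tab$beta_exp * flip
    y <- tab$beta_out * flip
    constrained <- lm(y ~ x - 1, weights = 1 / tab$se_out^2)
    expect_equal(unname(coef(constrained)[1]), mr_ivw(tab, "FE")$beta,
                 tolerance = 1e-12)
  }
})

test_that("weighted median interpolates the ratio distribution", {
  tab <- make_harmonized(3, seed = 2)
  tab$beta_exp <- 1; tab$se_exp <- 1e-8
  tab$beta_out <- c(0.1, 0.2, 0.3); tab$se_out <- 0.1
  est <- mr_weighted_median(tab, n_boot = 100, seed = 4)
  expect_equal(est$beta, 0.2)
  # equal weights with odd J equal the plain sample median
  tab5 <- make_harmonized(5, seed = 2)
  tab5$beta_exp <- 1; tab5$se_exp <- 1e-8; tab5$se_out <- 0.05
  tab5$beta_out <- c(0.4, 0.1, 0.25, 0.3, 0.15)
  expect_equal(mr_weighted_median(tab5, 100, seed = 4)$beta,
               median(tab5$beta_out))
})

test_that("weighted median resists a single wild outlier", {
  tab <- make_harmonized(10, seed = 6)
  tab$beta_exp <- 1; tab$se_exp <- 1e-8; tab$se_out <- 0.05
  tab$beta_out <- rep(0.2, 10)
  base <- mr_weighted_median(tab, 100, seed = 4)$beta
  tab$beta_out[10] <- 5  # displacement 4.8 on the ratio scale
  moved <- mr_weighted_median(tab, 100, seed = 4)$beta
  expect_lt(abs(moved - base), 0.1 * abs(5 - 0.2))
})

test_that("bootstrap standard errors are reproducible under the same seed", {
  tab <- make_harmonized(6, seed = 8)
  a <- mr_weighted_median(tab, 200, seed = 99)
  b <- mr_weighted_median(tab, 200, seed = 99)
  expect_identical(a$se, b$se)
  c1 <- mr_weighted_mode(tab, 1, 200, seed = 99)
  c2 <- mr_weighted_mode(tab, 1, 200, seed = 99)
  expect_identical(c1$se, c2$se)
})

test_that("weighted mode follows the dominant ratio cluster", {
  tab <- make_harmonized(9, seed = 10)
  tab$beta_exp <- 1; tab$se_exp <- 1e-8; tab$se_out <- 0.05
  tab$beta_out <- c(0.28, 0.29, 0.30, 0.30, 0.31, 0.32, 0.30, 1.0, 1.0)
  est <- mr_weighted_mode(tab, 1, 100, seed = 12)
  expect_lt(abs(est$beta - 0.30), 0.05)
  # all ratios identical: the estimate is that value
  tab$beta_out <- rep(0.25, 9)
  expect_equal(mr_weighted_mode(tab, 1, 100, seed = 12)$beta, 0.25)
})

test_that("weighted mode is invariant to instrument ordering", {
  tab <- make_harmonized(7, theta = 0.3, seed = 13)
  perm <- tab[sample(nrow(tab)), ]
  expect_equal(mr_weighted_mode(tab, 1, 100, seed = 5)$beta,
               mr_weighted_mode(perm, 1, 100, seed = 5)$beta)
})

test_that("the estimator battery respects method arity rules", {
  tab3 <- make_harmonized(3, seed = 14)
  all3 <- mr_estimate_all(tab3, n_boot = 100, seed = 2)
  expect_setequal(all3$method,
                  c("IVW_FE", "IVW_MRE", "EGGER", "WMEDIAN", "WMODE"))
  tab2 <- make_harmonized(2, seed = 14)
  all2 <- mr_estimate_all(tab2, n_boot = 100, seed = 2)
  expect_setequal(all2$method, c("IVW_FE", "IVW_MRE", "WMEDIAN"))
  # OR/CI fields are definitional transforms of beta and se
  expect_equal(all3$ci_low, exp(all3$beta - 1.959964 * all3$se),
               tolerance = 1e-12)
  expect_equal(all3$ci_high, exp(all3$beta + 1.959964 * all3$se),
               tolerance = 1e-12)
  expect_equal(all3$or_point, exp(all3$beta), tolerance = 1e-12)
})

test_that("all methods agree in sign on a clean strong-instrument set", {
  truth <- simulation_truth(theta = 0.25, j_snps = 20, seed = 404,
                            gamma_range = c(0.25, 0.4))
  tab <- sim_harmonized(truth)
  est <- mr_estimate_all(tab, n_boot = 200, seed = 7)
  expect_true(all(sign(est$beta) == 1))
})
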