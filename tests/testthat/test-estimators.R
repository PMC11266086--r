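test_that("Wald ratio matches hand arithmetic and guards gamma = 0", {
  est <- wald_ratio(0.25, 0.01, 0.5, 0.1)
  expect_equal(est$beta, 2)
  expect_equal(est$se, 0.4)
  expect_equal(est$ci_low, 2 - 1.96 * 0.4)
  expect_equal(wald_ratio(0.25, 0.01, 0, 0.1)$beta, 0)
  expect_error(wald_ratio(0, 0.01, 0.5, 0.1), "gamma")
})

test_that("second-order Wald SE dominates the first-order SE on a grid", {
  set.seed(5)
  for (i in 1:50) {
    g <- runif(1, 0.01, 0.5); sg <- runif(1, 0.001, 0.1)
    G <- rnorm(1, 0, 0.3); sG <- runif(1, 0.001, 0.1)
    expect_gte(wald_ratio(g, sg, G, sG, second_order = TRUE)$se,
               wald_ratio(g, sg, G, sG)$se)
  }
})

test_that("IVW reproduces hand arithmetic and degenerates to Wald", {
  two <- make_harmonized(c(1, 1), c(1, 3), sG = c(1, 1))
  est <- mr_ivw(two, mode = "fixed")
  expect_equal(est$beta, 2)
  expect_equal(est$se, sqrt(0.5))

  one <- make_harmonized(0.25, 0.5, sG = 0.1)
  expect_equal(mr_ivw(one)$beta, wald_ratio(0.25, 0.01, 0.5, 0.1)$beta)
  expect_equal(mr_ivw(one)$se, wald_ratio(0.25, 0.01, 0.5, 0.1)$se)

  expect_error(mr_ivw(make_harmonized(numeric(0), numeric(0))), "at least")
})

test_that("IVW equals an origin-regression WLS oracle on random data", {
  set.seed(17)
  for (i in 1:20) {
    k <- 50
    d <- make_harmonized(rnorm(k, 0.1, 0.05), rnorm(k, 0.02, 0.05),
                         sG = runif(k, 0.01, 0.2))
    oracle <- wls_oracle(matrix(d$beta_exposure, ncol = 1), d$beta_outcome,
                         1 / d$se_outcome^2)
    est <- mr_ivw(d, mode = "fixed")
    expect_equal(est$beta, oracle$beta, tolerance = 1e-12)
    expect_equal(est$se, sqrt(oracle$cov_unscaled[1, 1]), tolerance = 1e-12)
  }
})

test_that("fixed and MRE IVW share the point estimate; MRE SE never shrinks", {
  set.seed(23)
  d <- make_harmonized(rnorm(30, 0.1, 0.03), rnorm(30, 0.02, 0.1),
                       sG = runif(30, 0.01, 0.05))
  fixed <- mr_ivw(d, mode = "fixed")
  mre <- mr_ivw(d, mode = "mre")
  expect_equal(fixed$beta, mre$beta)
  expect_gte(mre$se, fixed$se)
})

test_that("auto IVW applies the heterogeneity switch", {
  set.seed(29)
  g <- runif(40, 0.05, 0.2)
  homog <- make_harmonized(g, 0.1 * g + rnorm(40, 0, 0.001), sG = rep(0.05, 40))
  expect_equal(mr_ivw(homog, mode = "auto")$method, "IVW-fixed")
  hetero <- make_harmonized(g, 0.1 * g + rnorm(40, 0, 0.5), sG = rep(0.05, 40))
  expect_equal(attr(mr_ivw(hetero, mode = "auto"), "q_pval") < 0.05, TRUE)
  expect_equal(mr_ivw(hetero, mode = "auto")$method, "IVW-MRE")
})

test_that("Egger fits collinear points exactly", {
  d <- make_harmonized(c(1, 2, 3), c(2, 3, 4), sG = rep(1, 3))
  est <- mr_egger(d)
  slope <- dplyr::filter(est, method == "Egger-slope")
  intercept <- dplyr::filter(est, method == "Egger-intercept")
  expect_equal(slope$beta, 1, tolerance = 1e-10)
  expect_equal(intercept$beta, 1, tolerance = 1e-10)
  expect_error(mr_egger(make_harmonized(c(1, 2), c(1, 2))), "at least 3")
})

test_that("Egger equals a generic WLS oracle with the dispersion clamp", {
  set.seed(31)
  for (i in 1:20) {
    k <- 50
    d <- make_harmonized(runif(k, 0.02, 0.3), rnorm(k, 0.05, 0.1),
                         sG = runif(k, 0.01, 0.2))
    w <- 1 / d$se_outcome^2
    oracle <- wls_oracle(cbind(1, d$beta_exposure), d$beta_outcome, w)
    scale <- max(1, sqrt(oracle$rss / (k - 2)))
    est <- mr_egger(d)
    slope <- dplyr::filter(est, method == "Egger-slope")
    intercept <- dplyr::filter(est, method == "Egger-intercept")
    expect_equal(slope$beta, oracle$beta[2], tolerance = 1e-10)
    expect_equal(intercept$beta, oracle$beta[1], tolerance = 1e-10)
    expect_equal(slope$se, sqrt(oracle$cov_unscaled[2, 2]) * scale,
                 tolerance = 1e-10)
    expect_equal(intercept$se, sqrt(oracle$cov_unscaled[1, 1]) * scale,
                 tolerance = 1e-10)
  }
})

test_that("weighted median interpolates the ratio at half weight", {
  d <- make_harmonized(c(1, 1, 1), c(1, 2, 3), sG = rep(1, 3))
  expect_equal(mr_weighted_median(d, n_boot = 10, seed = 1)$beta, 2)

  # one SNP holding > 50% of the weight dictates the estimate
  dom <- make_harmonized(c(1, 1, 1), c(1, 5, 9), sG = c(1, 0.01, 1))
  expect_equal(mr_weighted_median(dom, n_boot = 10, seed = 1)$beta, 5,
               tolerance = 0.05)

  expect_error(mr_weighted_median(make_harmonized(c(1, 1), c(1, 2))), "at least 3")
})

test_that("weighted median equals a weighted-quantile oracle on random sets", {
  set.seed(37)
  for (i in 1:20) {
    k <- 20
    d <- make_harmonized(runif(k, 0.05, 0.3), rnorm(k, 0.05, 0.1),
                         sG = runif(k, 0.01, 0.2))
    est <- mr_weighted_median(d, n_boot = 2, seed = 1)
    want <- weighted_quantile_oracle(d$beta_outcome / d$beta_exposure,
                                     d$beta_exposure^2 / d$se_outcome^2)
    expect_equal(est$beta, want, tolerance = 1e-12)
  }
})

test_that("weighted-median bootstrap SE is seed-stable", {
  d <- make_harmonized(runif(15, 0.05, 0.3), rnorm(15, 0.02, 0.05))
  a <- mr_weighted_median(d, n_boot = 100, seed = 5)
  b <- mr_weighted_median(d, n_boot = 100, seed = 5)
  expect_identical(a, b)
})

test_that("odds-ratio conversion exponentiates estimate and bounds", {
  est <- tibble::tibble(beta = 0, se = 0.1, ci_low = -0.196, ci_high = 0.196)
  or <- to_odds_ratio(est)
  expect_equal(or$or, 1)
  expect_equal(or$or_ci_low, exp(-0.196))
})

test_that("estimates are scale and sign equivariant", {
  set.seed(41)
  d <- make_harmonized(runif(20, 0.05, 0.3), rnorm(20, 0.05, 0.1),
                       sG = runif(20, 0.01, 0.1))
  for (c_mult in c(2, -1)) {
    d2 <- dplyr::mutate(d, beta_outcome = beta_outcome * c_mult,
                        se_outcome = se_outcome * abs(c_mult))
    expect_equal(mr_ivw(d2, "fixed")$beta, c_mult * mr_ivw(d, "fixed")$beta,
                 tolerance = 1e-12)
    expect_equal(mr_ivw(d2, "fixed")$se, abs(c_mult) * mr_ivw(d, "fixed")$se,
                 tolerance = 1e-12)
    s2 <- dplyr::filter(mr_egger(d2), method == "Egger-slope")
    s1 <- dplyr::filter(mr_egger(d), method == "Egger-slope")
    expect_equal(s2$beta, c_mult * s1$beta, tolerance = 1e-10)
    w2 <- mr_weighted_median(d2, n_boot = 2, seed = 1)
    w1 <- mr_weighted_median(d, n_boot = 2, seed = 1)
    expect_equal(w2$beta, c_mult * w1$beta, tolerance = 1e-12)
  }
})

test_that("Egger intercept magnitude is invariant under gamma orientation", {
  set.seed(43)
  d <- make_harmonized(rnorm(20, 0, 0.2), rnorm(20, 0.05, 0.1))
  flipped <- dplyr::mutate(d, beta_exposure = -beta_exposure,
                           beta_outcome = -beta_outcome)
  i1 <- dplyr::filter(mr_egger(d), method == "Egger-intercept")
  i2 <- dplyr::filter(mr_egger(flipped), method == "Egger-intercept")
  expect_equal(abs(i1$beta), abs(i2$beta), tolerance = 1e-12)
})

test_that("mr_all bundles the three estimators with tidy and glance", {
  sim <- simulate_two_sample(sim_config(n_snps = 50, seed = 3))
  fit <- mr_all(harmonize(sim$exposure, sim$outcome), n_boot = 50, seed = 1,
                exposure = "X", outcome = "Y")
  td <- tidy(fit)
  expect_setequal(td$method, c("IVW-fixed", "Egger-slope", "Egger-intercept",
                               "WeightedMedian"))
  expect_true(all(abs(td$ci_low - (td$beta - 1.96 * td$se)) < 1e-12))
  gl <- glance(fit)
  expect_equal(gl$nsnp, 50)
  expect_equal(gl$q_df, 49)
})
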