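test_that("Cochran Q matches hand arithmetic and degenerate cases", {
  two <- make_harmonized(c(1, 1), c(1, 3), sG = c(1, 1))
  q <- cochran_q(two, beta_ivw = 2)
  expect_equal(q$q_stat, 2)
  expect_equal(q$q_df, 1)

  same <- make_harmonized(c(1, 2), c(2, 4), sG = c(1, 1))
  q0 <- cochran_q(same)
  expect_equal(q0$q_stat, 0, tolerance = 1e-12)
  expect_equal(q0$q_pval, 1)

  expect_error(cochran_q(make_harmonized(1, 2)), "at least 2")
})

test_that("Q equals the weighted RSS of ratios around the IVW estimate", {
  set.seed(3)
  d <- make_harmonized(runif(30, 0.05, 0.3), rnorm(30, 0.03, 0.05),
                       sG = runif(30, 0.01, 0.1))
  est <- mr_ivw(d, mode = "fixed")
  w <- d$beta_exposure^2 / d$se_outcome^2
  rss <- sum(w * (d$beta_outcome / d$beta_exposure - est$beta)^2)
  expect_equal(cochran_q(d)$q_stat, rss, tolerance = 1e-10)
  expect_equal(attr(est, "q_stat"), rss, tolerance = 1e-10)
})

test_that("homogeneous simulations give Q/(k-1) near 1 on average", {
  set.seed(11)
  ratios <- vapply(1:200, function(i) {
    sim <- simulate_two_sample(sim_config(n_snps = 30, seed = 1000 + i))
    q <- cochran_q(harmonize(sim$exposure, sim$outcome))
    q$q_stat / q$q_df
  }, numeric(1))
  mc_se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 1), 3 * mc_se)
})

test_that("egger_intercept_test returns the intercept component", {
  set.seed(7)
  d <- make_harmonized(runif(10, 0.05, 0.3), rnorm(10, 0.03, 0.05))
  it <- egger_intercept_test(d)
  intercept <- dplyr::filter(mr_egger(d), method == "Egger-intercept")
  expect_equal(it$intercept, intercept$beta)
  expect_equal(it$pval, intercept$pval)
})

test_that("MR-PRESSO is deterministic under a fixed seed and guards n_sim", {
  set.seed(9)
  d <- make_harmonized(runif(10, 0.05, 0.3), rnorm(10, 0.03, 0.05))
  a <- mr_presso(d, n_sim = 200, seed = 4)
  b <- mr_presso(d, n_sim = 200, seed = 4)
  expect_identical(a[c("global_rss", "global_pval", "outlier_pvals")],
                   b[c("global_rss", "global_pval", "outlier_pvals")])
  expect_gte(a$global_pval, 1 / 201)
  expect_error(mr_presso(d, n_sim = 0), "positive")
  expect_error(mr_presso(make_harmonized(c(1, 1, 1), c(1, 2, 3))), "at least 4")
})

test_that("MR-PRESSO flags a spiked outlier and stays quiet on clean data", {
  sim <- simulate_two_sample(sim_config(n_snps = 50, seed = 13))
  h <- harmonize(sim$exposure, sim$outcome)
  clean <- mr_presso(h, n_sim = 1000, seed = 1)
  expect_length(clean$outlier_indices, 0)

  spiked <- h
  spiked$beta_outcome[7] <- spiked$beta_outcome[7] + 0.05
  pr <- mr_presso(spiked, n_sim = 1000, seed = 1)
  expect_true(7 %in% pr$outlier_indices)
  expect_lt(pr$global_pval, clean$global_pval)
  expect_false(is.na(pr$distortion_pval))
})

test_that("global p-value is non-increasing in outlier magnitude", {
  sim <- simulate_two_sample(sim_config(n_snps = 40, seed = 17))
  h <- harmonize(sim$exposure, sim$outcome)
  pvals <- vapply(c(0.005, 0.02, 0.08), function(mag) {
    spiked <- h
    spiked$beta_outcome[3] <- spiked$beta_outcome[3] + mag
    mr_presso(spiked, n_sim = 1000, seed = 2)$global_pval
  }, numeric(1))
  expect_true(all(diff(pvals) <= 0))
})

test_that("clean data passes through the outlier-removal loop unchanged", {
  sim <- simulate_two_sample(sim_config(n_snps = 40, seed = 19))
  h <- harmonized_kept(harmonize(sim$exposure, sim$outcome))
  out <- remove_outliers_until_clean(h, n_sim = 200, seed = 1)
  expect_equal(nrow(out$log), 0)
  expect_equal(out$data, h)
  expect_equal(out$status, "clean")
})

test_that("injected directional-pleiotropy SNPs are removed until clean", {
  sim <- simulate_two_sample(sim_config(n_snps = 40, seed = 1))
  h <- harmonized_kept(harmonize(sim$exposure, sim$outcome))
  # directional pleiotropy at the two weakest instruments, where it tilts
  # the Egger intercept rather than the slope
  j <- order(abs(h$beta_exposure))[1:2]
  h$beta_outcome[j] <- h$beta_outcome[j] + 0.025
  expect_lt(egger_intercept_test(h)$pval, 0.05)
  out <- remove_outliers_until_clean(h, n_sim = 1000, seed = 7)
  expect_setequal(out$removed_snps, h$snp[j])
  expect_gte(egger_intercept_test(out$data)$pval, 0.05)
  expect_equal(out$status, "clean")
  # log conserves removals
  expect_equal(sum(out$log$n_removed), length(out$removed_snps))
})

test_that("adversarial all-pleiotropic data terminates at max_rounds", {
  set.seed(29)
  k <- 12
  g <- runif(k, 0.05, 0.3)
  # strong directional pleiotropy on every SNP relative to tiny SEs
  G <- 0.1 * g + abs(rnorm(k, 0.05, 0.05))
  d <- make_harmonized(g, G, sG = rep(0.001, k))
  out <- suppressWarnings(
    remove_outliers_until_clean(d, max_rounds = 3, n_sim = 100, seed = 1)
  )
  expect_lte(nrow(out$log), 3)
  expect_true(out$status %in% c("max_rounds", "too_few_snps", "clean"))
  expect_true(nrow(out$data) >= 1)
})

test_that("leave-one-out reproduces pairwise IVW estimates at k = 3", {
  d <- make_harmonized(c(1, 1, 1), c(1, 2, 3), sG = c(1, 1, 1))
  loo <- leave_one_out(d, mode = "fixed")
  expect_equal(nrow(loo), 3)
  expect_equal(loo$snp_omitted, d$snp)
  for (j in 1:3) {
    expect_equal(loo$beta[j], mr_ivw(d[-j, ], mode = "fixed")$beta)
  }
  expect_equal(loo$beta[1], 2.5) # mean of ratios 2 and 3 at equal weights
  expect_error(leave_one_out(make_harmonized(c(1, 1), c(1, 2))), "at least 3")
})

test_that("a near-zero-weight SNP barely moves the estimate when dropped", {
  d <- make_harmonized(c(1, 1, 1e-6), c(1, 2, 5), sG = c(1, 1, 1))
  loo <- leave_one_out(d, mode = "fixed")
  full <- mr_ivw(d, mode = "fixed")
  expect_equal(loo$beta[3], full$beta, tolerance = 1e-5)
})

test_that("leave-one-out spread shrinks as the SNP count grows", {
  spreads <- vapply(c(10, 50, 200), function(k) {
    mean(vapply(1:5, function(s) {
      sim <- simulate_two_sample(sim_config(n_snps = k, seed = 30 + s))
      loo <- leave_one_out(harmonize(sim$exposure, sim$outcome), mode = "fixed")
      max(loo$beta) - min(loo$beta)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(spreads) < 0))
})

test_that("the sensitivity report bundles all diagnostics", {
  sim <- simulate_two_sample(sim_config(n_snps = 30, seed = 37))
  h <- harmonize(sim$exposure, sim$outcome)
  rep <- sensitivity_report(h, n_sim = 1000, seed = 1)
  td <- tidy(rep)
  expect_equal(td$nsnp, 30)
  expect_equal(td$q_df, 29)
  expect_equal(nrow(rep$loo), 30)
  expect_true(td$loo_beta_min <= td$loo_beta_max)
})
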