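test_that("standard errors are recovered from printed confidence intervals", {
  expect_equal(ci_to_se(-1.96, 1.96, z = 1.96), 1.0)
  expect_equal(ci_to_se(-stats::qnorm(0.975), stats::qnorm(0.975)), 1.0,
               tolerance = 1e-12)
  # printed DSST observed and STROOP IV intervals
  expect_equal(ci_to_se(0.024, 0.077, z = 1.96), 0.0135204, tolerance = 1e-6)
  expect_equal(ci_to_se(-1.125, -0.072, z = 1.96), 0.268622, tolerance = 1e-5)
  expect_error(ci_to_se(1, 1), "exceed")
})

test_that("the Wald ratio and its delta-method error behave as derived", {
  # null numerator
  expect_equal(wald_iv(list(beta = 0, se = 0.01),
                       list(beta = -0.05, se = 0.008))$beta_iv, 0)

  # printed STROOP arithmetic: reduced form / first stage
  iv <- wald_iv(list(beta = 0.0287, se = 0.00695),
                list(beta = -0.048, se = 0.008163))
  expect_equal(iv$beta_iv, -0.598, tolerance = 1e-3)
  expect_equal(iv$mode, "one_sample_wald")

  # exact first stage: se_iv collapses to se_GY / |b_GX|
  iv0 <- wald_iv(list(beta = 0.03, se = 0.005),
                 list(beta = -0.05, se = 1e-12))
  expect_equal(iv0$se_iv, 0.005 / 0.05, tolerance = 1e-6)

  # linearity in the numerator
  a <- 2.7
  iv_a <- wald_iv(list(beta = a * 0.0287, se = 0.00695),
                  list(beta = -0.048, se = 0.008163))
  expect_equal(iv_a$beta_iv, a * iv$beta_iv, tolerance = 1e-12)

  expect_error(wald_iv(list(beta = 0.03, se = 0.005),
                       list(beta = 0.001, se = 0.01)), "weak instrument.*F")
})

test_that("the instrument F statistic is the squared Wald z", {
  expect_equal(f_statistic(0.2, 0.1), 4)
  for (i in 1:20) {
    b <- rnorm(1); s <- runif(1, 0.01, 1)
    expect_equal(f_statistic(b, s), (b / s)^2, tolerance = 1e-12)
  }
  # from the printed pooled first stage: beta -0.048, CI (-0.064, -0.032)
  se <- ci_to_se(-0.064, -0.032, z = 1.96)
  expect_equal(f_statistic(-0.048, se), 34.57, tolerance = 0.01)
  expect_error(f_statistic(1, 0), "positive")
})

test_that("the observed-vs-causal difference Z-test reproduces all six printed rows", {
  tab <- engage_table2()
  for (i in seq_len(nrow(tab))) {
    obs <- list(beta = tab$obs_beta[i],
                se = ci_to_se(tab$obs_ci_low[i], tab$obs_ci_high[i], z = 1.96))
    iv <- list(beta = tab$iv_beta[i],
               se = ci_to_se(tab$iv_ci_low[i], tab$iv_ci_high[i], z = 1.96))
    d <- difference_test(obs, iv)
    expect_equal(round(d$p, 2), tab$diff_p[i],
                 label = paste("Diff-P for", tab$trait[i]))
    # antisymmetry
    d_rev <- difference_test(iv, obs)
    expect_equal(d_rev$z, -d$z, tolerance = 1e-12)
    expect_equal(d_rev$p, d$p, tolerance = 1e-12)
  }
  same <- difference_test(list(beta = 0.3, se = 0.1), list(beta = 0.3, se = 0.2))
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
})

test_that("the two-sample IVW estimator matches hand arithmetic and the one-SNP ratio", {
  est <- two_sample_ivw(x = c(0.1, 0.2), sx = c(0.01, 0.01),
                        y = c(0.05, 0.10), sy = c(1, 1))
  expect_equal(est$beta_iv, 0.5, tolerance = 1e-12)
  expect_equal(est$se_iv, 1 / sqrt(0.05), tolerance = 1e-12)

  # k = 1 reduces to the Wald ratio, with the exact-first-stage SE
  one <- two_sample_ivw(x = -0.05, sx = 0.004, y = 0.02, sy = 0.008)
  wald <- wald_iv(list(beta = 0.02, se = 0.008), list(beta = -0.05, se = 1e-14))
  expect_equal(one$beta_iv, wald$beta_iv, tolerance = 1e-12)
  expect_equal(one$se_iv, 0.008 / 0.05, tolerance = 1e-12)

  expect_error(two_sample_ivw(c(0, 0), c(1, 1), c(1, 1), c(1, 1)), "zero")
  expect_error(two_sample_ivw(0.1, 0.01, c(1, 2), c(1, 1)), "equal length")

  z_only <- two_sample_ivw(x = c(-0.05, -0.06), sx = c(0.004, 0.004),
                           y = c(1.2, 0.8), mode = "zscore")
  expect_equal(z_only$mode, "two_sample_zscore")
  expect_equal(z_only$z, z_only$beta_iv / z_only$se_iv)
})

test_that("noise-free summary statistics return the causal effect exactly", {
  truth <- true_params(theta = 0.086)
  ss <- simulate_two_sample_summary(truth = truth, n_x = 37684, n_y = 53949,
                                    trait = "GENERAL", seed = 1, noise = FALSE)
  est <- two_sample_ivw(ss$exposure$beta, ss$exposure$se,
                        ss$outcome$beta, ss$outcome$se)
  expect_equal(est$beta_iv, 0.086, tolerance = 1e-12)
})

test_that("the per-SNP ratio scan flags pleiotropic outliers and is calibrated", {
  # identical ratios: no heterogeneity
  flat <- per_snp_ratio_scan(x = c(0.1, 0.2), sx = c(0.01, 0.01),
                             y = c(0.05, 0.10), sy = c(0.01, 0.01))
  expect_equal(flat$q, 0, tolerance = 1e-20)

  # one SNP given a large direct effect dominates Q
  snps <- default_snps(beta_tl = -0.1)
  ss <- simulate_two_sample_summary(snps, true_params(theta = 0.1),
                                    n_x = 2e5, n_y = 2e5, seed = 2)
  y <- ss$outcome$beta; y[4] <- y[4] + 0.05
  scan <- per_snp_ratio_scan(ss$exposure$beta, ss$exposure$se, y, ss$outcome$se)
  expect_equal(scan$max_contributor, 4)
  expect_lt(scan$p, 0.01)

  # zero exposure effect skipped with a warning
  expect_warning(
    skipped <- per_snp_ratio_scan(c(0, 0.1, 0.2), c(0.01, 0.01, 0.01),
                                  c(0, 0.05, 0.1), c(0.01, 0.01, 0.01)),
    "zero exposure")
  expect_equal(nrow(skipped$ratios), 2)

  # no pleiotropy: Q p-values uniform across replicates (strong instrument)
  ps <- vapply(1:200, function(i) {
    s <- simulate_two_sample_summary(snps, true_params(theta = 0.1),
                                     n_x = 2e5, n_y = 2e5, seed = 5000 + i)
    per_snp_ratio_scan(s$exposure$beta, s$exposure$se,
                       s$outcome$beta, s$outcome$se)$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
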